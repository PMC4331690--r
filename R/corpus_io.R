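# Reading and writing abstracts, gold annotations and prediction files
# (mention-level CEM and document-indexing CDI formats), with strict
# validation against the section texts.
#
# All files are UTF-8 TSV without headers. Offsets on disk may be 0- or
# 1-based (`offset_base`); in memory they are always 0-based half-open.

.sections <- c("T", "A")

.read_tsv_lines <- function(path, n_fields, what) {
  if (!file.exists(path)) {
    stop("file not found: ", path)
  }
  lines <- readLines(path, encoding = "UTF-8", warn = FALSE)
  lines <- lines[nzchar(lines)]
  fields <- strsplit(lines, "\t", fixed = TRUE)
  bad <- which(lengths(fields) != n_fields)
  if (length(bad) > 0L) {
    stop(
      "malformed ", what, " line ", bad[1L], ": expected ", n_fields,
      " tab-separated fields, got ", lengths(fields)[bad[1L]]
    )
  }
  fields
}

#' Read an abstracts file
#'
#' One document per line: `doc_id`, `title`, `abstract`, tab-separated.
#'
#' @param path Path to the abstracts TSV.
#' @return A tibble with columns `doc_id`, `title`, `abstract`, one row per
#'   line, order preserved.
#' @export
read_abstracts <- function(path) {
  fields <- .read_tsv_lines(path, 3L, "abstracts")
  out <- tibble::tibble(
    doc_id = vapply(fields, `[[`, character(1), 1L),
    title = vapply(fields, `[[`, character(1), 2L),
    abstract = vapply(fields, `[[`, character(1), 3L)
  )
  if (any(!nzchar(out$doc_id))) {
    stop("empty doc_id on line ", which(!nzchar(out$doc_id))[1L])
  }
  dup <- duplicated(out$doc_id)
  if (any(dup)) {
    stop("duplicate doc_id in abstracts file: ", out$doc_id[dup][1L])
  }
  out
}

#' Write an abstracts file
#'
#' @param documents A document tibble (`doc_id`, `title`, `abstract`).
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_abstracts <- function(documents, path) {
  bad <- grepl("[\t\n\r]", documents$title) | grepl("[\t\n\r]", documents$abstract)
  if (any(bad)) {
    stop("title/abstract may not contain tabs or newlines (doc ",
      documents$doc_id[bad][1L], ")")
  }
  writeLines(
    paste(documents$doc_id, documents$title, documents$abstract, sep = "\t"),
    path, useBytes = TRUE
  )
  invisible(path)
}

.section_text <- function(documents, doc_id, section) {
  i <- match(doc_id, documents$doc_id)
  ifelse(section == "T", documents$title[i], documents$abstract[i])
}

#' Read a gold annotations file
#'
#' One mention per line: `doc_id`, section flag (`T` for title, `A` for
#' abstract), start, end, mention text, category. Every mention is validated
#' against the referenced section text: the span must be inside the section
#' and the stored text must equal the substring at the span, compared
#' exactly.
#'
#' @param path Path to the annotations TSV.
#' @param documents The corpus the annotations refer to, from
#'   [read_abstracts()].
#' @param offset_base Offset convention used in the file: `0` (default) or
#'   `1`.
#' @return A mention tibble: `doc_id`, `section`, `start`, `end` (0-based,
#'   half-open), `text`, `category`.
#' @export
read_annotations <- function(path, documents, offset_base = 0L) {
  stopifnot(offset_base %in% c(0L, 1L))
  fields <- .read_tsv_lines(path, 6L, "annotations")
  out <- tibble::tibble(
    doc_id = vapply(fields, `[[`, character(1), 1L),
    section = vapply(fields, `[[`, character(1), 2L),
    start = suppressWarnings(as.integer(vapply(fields, `[[`, character(1), 3L))) - as.integer(offset_base),
    end = suppressWarnings(as.integer(vapply(fields, `[[`, character(1), 4L))) - as.integer(offset_base),
    text = vapply(fields, `[[`, character(1), 5L),
    category = vapply(fields, `[[`, character(1), 6L)
  )
  if (anyNA(out$start) || anyNA(out$end)) {
    stop("non-numeric offsets on annotations line ",
      which(is.na(out$start) | is.na(out$end))[1L])
  }
  validate_mentions(out, documents)
  out
}

#' Validate mentions against a corpus
#'
#' Checks every mention invariant: known document, valid section flag and
#' category, span inside the section, and surface text equal to the section
#' substring at the span.
#'
#' @param mentions A mention tibble.
#' @param documents The corpus tibble.
#' @return `mentions`, invisibly, or an error describing the first violation.
#' @export
validate_mentions <- function(mentions, documents) {
  if (nrow(mentions) == 0L) {
    return(invisible(mentions))
  }
  unknown <- !(mentions$doc_id %in% documents$doc_id)
  if (any(unknown)) {
    stop("annotation references unknown doc_id: ", mentions$doc_id[unknown][1L])
  }
  bad_sec <- !(mentions$section %in% .sections)
  if (any(bad_sec)) {
    stop("invalid section flag (must be T or A): ", mentions$section[bad_sec][1L])
  }
  bad_cat <- !(mentions$category %in% chem_categories)
  if (any(bad_cat)) {
    stop("unknown category: ", mentions$category[bad_cat][1L])
  }
  sec_text <- .section_text(documents, mentions$doc_id, mentions$section)
  len <- nchar(sec_text)
  bad_span <- !(mentions$start >= 0L & mentions$start < mentions$end &
    mentions$end <= len)
  if (any(bad_span)) {
    i <- which(bad_span)[1L]
    stop(
      "offset error in ", mentions$doc_id[i], " [", mentions$start[i], ",",
      mentions$end[i], "): span outside section of length ", len[i]
    )
  }
  sub <- substr(sec_text, mentions$start + 1L, mentions$end)
  mismatch <- sub != mentions$text
  if (any(mismatch)) {
    i <- which(mismatch)[1L]
    stop(
      "offset error in ", mentions$doc_id[i], " [", mentions$start[i], ",",
      mentions$end[i], "): text \"", mentions$text[i],
      "\" does not match section substring \"", sub[i], "\""
    )
  }
  invisible(mentions)
}

#' Write a gold annotations file
#'
#' @param mentions A mention tibble.
#' @param path Output path.
#' @param offset_base Offset convention to write: `0` (default) or `1`.
#' @return `path`, invisibly.
#' @export
write_annotations <- function(mentions, path, offset_base = 0L) {
  writeLines(
    paste(mentions$doc_id, mentions$section,
      mentions$start + as.integer(offset_base),
      mentions$end + as.integer(offset_base),
      mentions$text, mentions$category,
      sep = "\t"
    ),
    path, useBytes = TRUE
  )
  invisible(path)
}

# Deterministic per-document ranking of CEM mentions: descending confidence,
# ties by (section, start, end) ascending with T before A.
.rank_cem <- function(mentions) {
  sec_ord <- match(mentions$section, .sections)
  mentions |>
    dplyr::mutate(.sec = sec_ord) |>
    dplyr::group_by(.data$doc_id) |>
    dplyr::arrange(dplyr::desc(.data$confidence), .data$.sec, .data$start,
      .data$end, .by_group = TRUE
    ) |>
    dplyr::mutate(rank = dplyr::row_number()) |>
    dplyr::ungroup() |>
    dplyr::select(-".sec")
}

#' Write mention-level (CEM) predictions
#'
#' One line per predicted mention: `doc_id`, `section:start:end` locator,
#' per-document rank by descending confidence (ties broken by ascending
#' section, start, end so output is byte-stable), confidence.
#'
#' @param mentions A mention tibble with a `confidence` column.
#' @param path Output path.
#' @param offset_base Offset convention to write.
#' @return `path`, invisibly.
#' @export
write_cem_predictions <- function(mentions, path, offset_base = 0L) {
  if (nrow(mentions) > 0L &&
    (!"confidence" %in% names(mentions) || anyNA(mentions$confidence))) {
    stop("CEM predictions require a confidence for every mention")
  }
  ranked <- if (nrow(mentions) == 0L) mentions else .rank_cem(mentions)
  lines <- if (nrow(ranked) == 0L) {
    character(0)
  } else {
    paste(
      ranked$doc_id,
      paste(ranked$section,
        ranked$start + as.integer(offset_base),
        ranked$end + as.integer(offset_base),
        sep = ":"
      ),
      ranked$rank,
      sprintf("%.6g", ranked$confidence),
      sep = "\t"
    )
  }
  writeLines(lines, path, useBytes = TRUE)
  invisible(path)
}

#' Read a CEM predictions file
#'
#' @param path Path to the predictions TSV written by
#'   [write_cem_predictions()].
#' @param offset_base Offset convention used in the file.
#' @return A tibble with `doc_id`, `section`, `start`, `end`, `rank`,
#'   `confidence`.
#' @export
read_cem_predictions <- function(path, offset_base = 0L) {
  fields <- .read_tsv_lines(path, 4L, "CEM predictions")
  loc <- strsplit(vapply(fields, `[[`, character(1), 2L), ":", fixed = TRUE)
  bad <- which(lengths(loc) != 3L)
  if (length(bad) > 0L) {
    stop("malformed locator on CEM line ", bad[1L])
  }
  tibble::tibble(
    doc_id = vapply(fields, `[[`, character(1), 1L),
    section = vapply(loc, `[[`, character(1), 1L),
    start = as.integer(vapply(loc, `[[`, character(1), 2L)) - as.integer(offset_base),
    end = as.integer(vapply(loc, `[[`, character(1), 3L)) - as.integer(offset_base),
    rank = as.integer(vapply(fields, `[[`, character(1), 3L)),
    confidence = as.numeric(vapply(fields, `[[`, character(1), 4L))
  )
}

#' Convert CEM predictions to document-indexing (CDI) records
#'
#' Per document, duplicate entity strings are removed keeping the maximum
#' confidence among duplicates, and the unique entities are sorted by
#' descending confidence (ties by text, exact comparison, no case folding)
#' and ranked 1..k.
#'
#' @param mentions A mention tibble with `confidence`.
#' @return A tibble with `doc_id`, `text`, `rank`, `confidence`.
#' @examples
#' cem_to_cdi(tibble::tibble(
#'   doc_id = "D1", section = "A", start = c(0L, 10L, 20L), end = c(7L, 17L, 29L),
#'   text = c("aspirin", "aspirin", "ibuprofen"), category = "TRIVIAL",
#'   confidence = c(0.9, 0.7, 0.8)
#' ))
#' @export
cem_to_cdi <- function(mentions) {
  if (nrow(mentions) == 0L) {
    return(tibble::tibble(
      doc_id = character(), text = character(),
      rank = integer(), confidence = numeric()
    ))
  }
  if (!"confidence" %in% names(mentions) || anyNA(mentions$confidence)) {
    stop("CDI conversion requires a confidence for every mention")
  }
  mentions |>
    dplyr::group_by(.data$doc_id, .data$text) |>
    dplyr::summarise(confidence = max(.data$confidence), .groups = "drop") |>
    dplyr::group_by(.data$doc_id) |>
    dplyr::arrange(dplyr::desc(.data$confidence), .data$text, .by_group = TRUE) |>
    dplyr::mutate(rank = dplyr::row_number()) |>
    dplyr::ungroup() |>
    dplyr::select("doc_id", "text", "rank", "confidence")
}

#' Write document-indexing (CDI) predictions
#'
#' @param records A CDI tibble (`doc_id`, `text`, `rank`, `confidence`),
#'   e.g. from [cem_to_cdi()].
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_cdi_predictions <- function(records, path) {
  .validate_cdi(records)
  lines <- if (nrow(records) == 0L) {
    character(0)
  } else {
    ord <- order(records$doc_id, records$rank)
    records <- records[ord, ]
    paste(records$doc_id, records$text, records$rank,
      sprintf("%.6g", records$confidence),
      sep = "\t"
    )
  }
  writeLines(lines, path, useBytes = TRUE)
  invisible(path)
}

.validate_cdi <- function(records) {
  if (nrow(records) == 0L) {
    return(invisible(records))
  }
  dup <- duplicated(records[, c("doc_id", "text")])
  if (any(dup)) {
    stop(
      "duplicate (doc_id, text) in CDI records: ", records$doc_id[dup][1L],
      " / ", records$text[dup][1L]
    )
  }
  by_doc <- split(seq_len(nrow(records)), records$doc_id)
  for (idx in by_doc) {
    r <- sort(records$rank[idx])
    if (!identical(r, seq_along(idx))) {
      stop("CDI ranks are not consecutive 1..k in document ",
        records$doc_id[idx][1L])
    }
    conf <- records$confidence[idx][order(records$rank[idx])]
    if (is.unsorted(rev(conf))) {
      stop("CDI confidence is not non-increasing with rank in document ",
        records$doc_id[idx][1L])
    }
  }
  invisible(records)
}

#' Read a CDI predictions file
#'
#' @param path Path to the CDI TSV.
#' @return A tibble with `doc_id`, `text`, `rank`, `confidence`, validated
#'   (unique text per document, consecutive ranks, non-increasing
#'   confidence).
#' @export
read_cdi_predictions <- function(path) {
  fields <- .read_tsv_lines(path, 4L, "CDI predictions")
  out <- tibble::tibble(
    doc_id = vapply(fields, `[[`, character(1), 1L),
    text = vapply(fields, `[[`, character(1), 2L),
    rank = as.integer(vapply(fields, `[[`, character(1), 3L)),
    confidence = as.numeric(vapply(fields, `[[`, character(1), 4L))
  )
  .validate_cdi(out)
  out
}

#' Read a token-annotation sidecar (POS/chunk)
#'
#' Six tab-separated columns: `doc_id`, section flag, start, end, POS tag,
#' chunk tag; spans are 0-based half-open.
#'
#' @param path Path to the sidecar TSV.
#' @return A tibble usable with [attach_pos()].
#' @export
read_token_annotations <- function(path) {
  fields <- .read_tsv_lines(path, 6L, "token annotations")
  tibble::tibble(
    doc_id = vapply(fields, `[[`, character(1), 1L),
    section = vapply(fields, `[[`, character(1), 2L),
    start = as.integer(vapply(fields, `[[`, character(1), 3L)),
    end = as.integer(vapply(fields, `[[`, character(1), 4L)),
    pos = vapply(fields, `[[`, character(1), 5L),
    chunk = vapply(fields, `[[`, character(1), 6L)
  )
}

#' Write a token-annotation sidecar
#'
#' @param annotations A tibble with `doc_id`, `section`, `start`, `end`,
#'   `pos`, `chunk`.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_token_annotations <- function(annotations, path) {
  writeLines(
    paste(annotations$doc_id, annotations$section, annotations$start,
      annotations$end, annotations$pos, annotations$chunk,
      sep = "\t"
    ),
    path, useBytes = TRUE
  )
  invisible(path)
}
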