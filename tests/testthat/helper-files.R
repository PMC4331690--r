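# Shared file fixtures built in code.

write_lines_tmp <- function(lines) {
  path <- withr::local_tempfile(fileext = ".tsv", .local_envir = parent.frame())
  writeLines(lines, path, useBytes = TRUE)
  path
}
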