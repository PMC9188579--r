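`%||%` <- function(a, b) if (is.null(a)) b else a

# FNV-1a hash of a character scalar, returned as 8 hex digits.
# Used to stamp output files with the effective run configuration.
fnv1a <- function(s) {
  bytes <- utf8ToInt(enc2utf8(s))
  h <- 2166136261
  for (b in bytes) {
    # xor on the low byte only (bitwXor cannot take values >= 2^31)
    h <- h - h %% 256 + bitwXor(h %% 256, b)
    # 32-bit modular multiply by the FNV prime 16777619, done in two
    # 16-bit halves to stay inside double precision
    lo <- h %% 65536; hi <- h %/% 65536
    h <- (lo * 16777619 + (hi * 16777619 %% 65536) * 65536) %% 4294967296
  }
  sprintf("%04x%04x", as.integer(h %/% 65536), as.integer(h %% 65536))
}

config_hash <- function(config) {
  fnv1a(as.character(jsonlite::toJSON(config, auto_unbox = TRUE, digits = NA,
                                      force = TRUE)))
}

# write a data.frame as CSV with a leading config-hash comment line
write_stamped_csv <- function(df, path, hash) {
  con <- file(path, open = "wt")
  on.exit(close(con))
  writeLines(sprintf("# config_hash %s", hash), con)
  utils::write.csv(df, con, row.names = FALSE)
  invisible(path)
}

read_stamped_csv <- function(path) {
  utils::read.csv(path, comment.char = "#", stringsAsFactors = FALSE)
}

# sorted items <-> canonical "A;B;C" key
items_key <- function(items) paste(sort(items), collapse = ";")
key_items <- function(key) strsplit(key, ";", fixed = TRUE)[[1L]]
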