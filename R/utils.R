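## small internal helpers shared across modules

`%||%` <- function(a, b) if (is.null(a)) b else a

stop_validation <- function(...) {
  stop(structure(class = c("memcontact_validation_error", "error", "condition"),
                 list(message = paste0(...), call = sys.call(-1))))
}

stop_parse <- function(...) {
  stop(structure(class = c("memcontact_parse_error", "error", "condition"),
                 list(message = paste0(...), call = sys.call(-1))))
}

assert_scalar_number <- function(x, name, positive = FALSE) {
  if (!is.numeric(x) || length(x) != 1L || !is.finite(x))
    stop_validation(name, " must be a single finite number")
  if (positive && x <= 0)
    stop_validation(name, " must be > 0")
  invisible(x)
}

## write a data.frame as a plain TSV (no quoting, no row names) so pipeline
## outputs are byte-stable across runs
write_tsv <- function(x, path) {
  write.table(x, path, sep = "\t", quote = FALSE, row.names = FALSE,
              col.names = TRUE)
  invisible(path)
}

## deterministic per-replicate seed derivation: root + index, kept in 32-bit
## integer range
replicate_seed <- function(seed, replicate) {
  as.integer((as.numeric(seed) + as.numeric(replicate)) %% .Machine$integer.max)
}
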