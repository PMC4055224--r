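# shared internal helpers

edge_key <- function(from, to) paste0(from, "->", to)

split_edge <- function(edge) {
  parts <- strsplit(edge, "->", fixed = TRUE)[[1]]
  if (length(parts) != 2L) {
    abort(paste0("`edge` must look like \"LTS->W\", got \"", edge, "\""))
  }
  c(from = parts[[1]], to = parts[[2]])
}

# Deterministic named sub-seeds derived from one root seed, so independent
# pipeline stages (generation, split, DES) get independent streams.
substream_seeds <- function(seed, labels) {
  stopifnot(length(seed) == 1L, is.finite(seed))
  old <- if (exists(".Random.seed", envir = globalenv())) {
    get(".Random.seed", envir = globalenv())
  }
  on.exit(if (!is.null(old)) assign(".Random.seed", old, envir = globalenv()))
  set.seed(as.integer(seed %% (.Machine$integer.max - 1L)))
  setNames(sample.int(.Machine$integer.max - 1L, length(labels)), labels)
}

assert_columns <- function(data, cols, what = "input") {
  missing <- setdiff(cols, names(data))
  if (length(missing) > 0L) {
    abort(paste0(what, " is missing column(s): ", paste(missing, collapse = ", ")))
  }
  invisible(data)
}
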