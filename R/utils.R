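## Internal helpers shared across modules.

## Run `code` under a fixed RNG seed without disturbing the caller's RNG
## stream.  All randomised operations in the package route through this so
## that a (function, seed) pair is fully reproducible.
withSeed <- function(seed, code) {
  withr::with_seed(as.integer(seed), code)
}

## A bulk table is a plain genes x samples numeric matrix with unique
## dimnames; validated at every module boundary that consumes one.
assertBulkTable <- function(table, arg = "table") {
  if (!is.matrix(table) || !is.numeric(table))
    stop(sprintf("'%s' must be a numeric genes x samples matrix", arg))
  if (is.null(rownames(table)) || is.null(colnames(table)))
    stop(sprintf("'%s' must have gene row names and sample column names", arg))
  if (anyDuplicated(rownames(table)))
    stop(sprintf("duplicate gene ids in '%s': %s", arg,
                 paste(unique(rownames(table)[duplicated(rownames(table))]),
                       collapse = ", ")))
  if (anyDuplicated(colnames(table)))
    stop(sprintf("duplicate sample labels in '%s'", arg))
  if (any(!is.finite(table)))
    stop(sprintf("'%s' contains non-finite values", arg))
  if (any(table < 0))
    stop(sprintf("'%s' contains negative values", arg))
  invisible(table)
}

assertGenesPresent <- function(table, genes, what = "gene") {
  missing <- setdiff(genes, rownames(table))
  if (length(missing))
    stop(sprintf("%s(s) not found in table: %s", what,
                 paste(missing, collapse = ", ")))
  invisible(TRUE)
}

## Format numbers for text output: up to 6 significant digits, trailing
## zeros trimmed (free-form floats, the dialect ImageJ's Text Image accepts).
formatCompact <- function(x) {
  out <- formatC(signif(x, 6L), format = "fg", flag = "#", digits = 6L)
  out <- sub("\\.?0+$", "", out)
  out[x == 0] <- "0"
  out
}
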