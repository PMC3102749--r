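# Internal helpers shared across modules.

# Run an expression under a fixed RNG seed, restoring the caller's RNG state.
# seed = NULL means "use the current RNG stream" (no restore).
with_seed <- function(seed, expr) {
  if (is.null(seed)) return(expr)
  if (!is.numeric(seed) || length(seed) != 1L || is.na(seed)) {
    stop("`seed` must be a single non-missing number or NULL", call. = FALSE)
  }
  has_seed <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  if (has_seed) {
    old <- get(".Random.seed", envir = globalenv(), inherits = FALSE)
    on.exit(assign(".Random.seed", old, envir = globalenv()), add = TRUE)
  } else {
    on.exit(rm(".Random.seed", envir = globalenv()), add = TRUE)
  }
  set.seed(as.integer(seed))
  expr
}

stopf <- function(fmt, ...) stop(sprintf(fmt, ...), call. = FALSE)

# strand normalisation: accepts W/C (Watson/Crick) or +/-
normalize_strand <- function(strand) {
  s <- toupper(as.character(strand))
  s[s == "+"] <- "W"
  s[s == "-"] <- "C"
  bad <- !s %in% c("W", "C")
  if (any(bad)) {
    stopf("invalid strand value(s): %s (use W/C or +/-)",
          paste(unique(strand[bad]), collapse = ", "))
  }
  s
}

# character-vector view of a DNA sequence (accepts character or Biostrings)
as_dna_chars <- function(x, arg = "sequence") {
  if (methods::is(x, "XString") || methods::is(x, "XStringSet")) {
    x <- as.character(x)
  }
  if (!is.character(x)) stopf("`%s` must be a character string or DNAString", arg)
  if (length(x) == 1L) x <- strsplit(x, "", fixed = TRUE)[[1L]]
  toupper(x)
}
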