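# internal helpers shared across modules

#' @importFrom stats predict rnorm runif sd var
#' @importFrom utils head read.delim
NULL

sigmoid <- function(x) 1 / (1 + exp(-x))

# Deterministic sub-seed derivation so every stochastic step of a run is a
# pure function of the single user-supplied seed. Kept below 2^31 - 1.
derive_seed <- function(seed, salt) {
  as.integer((as.numeric(seed) * 48271 + as.numeric(salt) * 16807) %% 2147483629L + 1)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

stopf <- function(fmt, ...) stop(sprintf(fmt, ...), call. = FALSE)

warnf <- function(fmt, ...) warning(sprintf(fmt, ...), call. = FALSE)

# stratified index split: returns logical vector, TRUE = held out
stratified_holdout <- function(y, fraction, seed) {
  idx <- withr::with_seed(seed, {
    unlist(lapply(unique(y), function(cl) {
      members <- which(y == cl)
      n_hold <- round(fraction * length(members))
      sample(members, n_hold)
    }), use.names = FALSE)
  })
  hold <- logical(length(y))
  hold[idx] <- TRUE
  hold
}
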