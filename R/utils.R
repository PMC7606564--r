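#' @keywords internal
"_PACKAGE"

#' Derive a stage-specific RNG seed from a global seed
#'
#' One global seed fans out to per-stage seeds by a stable arithmetic hash of
#' the stage name, so individual pipeline stages can be rerun in isolation
#' while remaining fully deterministic.
#'
#' @param seed Integer global seed.
#' @param stage Character stage name.
#' @return An integer seed in `[0, 2^31 - 2]`.
#' @export
stage_seed <- function(seed, stage) {
  stopifnot(is.numeric(seed), length(seed) == 1L, is.character(stage))
  h <- 0
  for (k in utf8ToInt(stage)) h <- (h * 131 + k) %% 2147483647
  as.integer((abs(seed) %% 2147483647 * 7919 + h) %% 2147483647)
}

#' @keywords internal
log_msg <- function(...) {
  message("[nadscape] ", ...)
}

## Strand sign: +1 on the plus strand, -1 on the minus strand.  All
## orientation helpers multiply by it so scalar strands recycle against
## vector positions.
strand_sign <- function(strand) {
  ifelse(strand == "+", 1L, -1L)
}

## 5' end of a read in 0-based genomic coordinates
read_five_prime <- function(start, end, strand) {
  s <- strand_sign(strand)
  (start + end - 1L) / 2 - s * (end - 1L - start) / 2
}

## 3' end of a read in 0-based genomic coordinates
read_three_prime <- function(start, end, strand) {
  s <- strand_sign(strand)
  (start + end - 1L) / 2 + s * (end - 1L - start) / 2
}

## Transcript-leader length of a genomic position relative to the TLS,
## measured in transcript orientation (positive = upstream of the TLS).
tl_length <- function(pos, tls, strand) {
  strand_sign(strand) * (tls - pos)
}

## Signed transcript-orientation offset of `pos` relative to `origin`
## (positive = downstream of origin).
tx_offset <- function(pos, origin, strand) {
  strand_sign(strand) * (pos - origin)
}

## Genomic position lying `offset` nt downstream of `origin` in transcript
## orientation.
tx_shift <- function(origin, offset, strand) {
  origin + strand_sign(strand) * offset
}

#' @keywords internal
`%||%` <- function(a, b) if (is.null(a)) b else a

## Statistical mode of an integer vector; ties broken by the supplied
## function of the tied values (default: smallest).
modal_value <- function(x, tie_break = min) {
  tab <- table(x)
  cand <- as.integer(names(tab)[tab == max(tab)])
  if (length(cand) == 1L) cand else tie_break(cand)
}
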