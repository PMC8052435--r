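# IUPAC nucleotide ambiguity codes and small sequence utilities.

.iupac_sets <- list(
  A = "A", C = "C", G = "G", T = "T",
  R = c("A", "G"), Y = c("C", "T"), S = c("C", "G"), W = c("A", "T"),
  K = c("G", "T"), M = c("A", "C"),
  B = c("C", "G", "T"), D = c("A", "G", "T"), H = c("A", "C", "T"),
  V = c("A", "C", "G"), N = c("A", "C", "G", "T")
)

.iupac_code_of <- local({
  m <- vapply(.iupac_sets, function(s) paste(sort(s), collapse = ""), character(1))
  stats::setNames(names(m), m)
})

#' IUPAC code for a set of bases
#'
#' @param bases Character vector of bases drawn from A, C, G, T.
#' @return Single-letter IUPAC ambiguity code covering exactly that set.
#' @examples
#' iupac_code(c("A", "G"))  # "R"
#' @export
iupac_code <- function(bases) {
  bases <- unique(toupper(bases))
  if (length(bases) == 0) return("N")
  key <- paste(sort(bases), collapse = "")
  code <- .iupac_code_of[[key]]
  if (is.null(code)) abort(paste0("no IUPAC code for base set {", key, "}"))
  code
}

#' Base set denoted by an IUPAC code
#'
#' @param code Single-letter IUPAC code.
#' @return Character vector of bases.
#' @export
iupac_bases <- function(code) {
  s <- .iupac_sets[[toupper(code)]]
  if (is.null(s)) abort(paste0("unknown IUPAC code: ", code))
  s
}

#' Reverse complement
#'
#' Vectorised reverse complement honouring IUPAC ambiguity codes and gaps.
#'
#' @param x Character vector of nucleotide sequences.
#' @return Character vector of reverse complements.
#' @export
revcomp <- function(x) {
  cpp_revcomp(toupper(x))
}

# uniform random DNA, used throughout the simulator and tests; stringi's
# generator runs on R's RNG, so set.seed() determinism carries through
random_dna <- function(n) {
  if (n == 0) return("")
  stringi::stri_rand_strings(1, n, pattern = "[ACGT]")
}
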