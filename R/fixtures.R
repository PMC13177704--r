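# Built-in motif fixtures.
#
# The published degenerate 36-mer consensus and the CA Pattern-1/Pattern-2
# motifs are not printed in the primary literature this package follows; the
# strings below are synthetic stand-ins designed to have the same structural
# properties (a degenerate 36 bp unit; a 37 bp Pattern 1 and a shorter
# Pattern 2 of near-equal A/C composition distinct from telomeric repeats).
# Any degenerate motif of the right shape exercises the scanners identically.

#' Degenerate 36-mer repeat consensus (synthetic stand-in)
#'
#' A fixed 36 bp consensus with IUPAC ambiguity codes, used to seed the
#' sliding edit-distance scan for the internal Y' repeat stretch.
#' @return single character string of length 36.
#' @export
yprime_motif_36mer <- function() {
  "ACWGTGNACMATGCCRTTCANGGYTAWCGSTAKCAN"
}

#' CA-rich repeat patterns (synthetic stand-ins)
#'
#' Pattern 1 spans 37 bp; Pattern 2 is shorter and shares its second half
#' with Pattern 1.  Both have near-equal adenine/cytosine composition
#' (A ~ 46%, C ~ 41%), clearly distinct from telomeric CA tracts
#' (C:A ~ 62.5:37.5), and are structured so that runs of telomere-like
#' C(1-3)A units stay short.
#' @return named character vector with elements `P1` and `P2`.
#' @export
ca_patterns <- function() {
  c(P1 = "CAACCAAGCACCAATCAACCACAAGCAACCTCAGCAA",
    P2 = "CCAAACACAAGCCACAAGCAACCTCAGCAAA")
}

iupac_sets <- list(A = "A", C = "C", G = "G", T = "T",
                   R = c("A", "G"), Y = c("C", "T"), S = c("C", "G"),
                   W = c("A", "T"), K = c("G", "T"), M = c("A", "C"),
                   B = c("C", "G", "T"), D = c("A", "G", "T"),
                   H = c("A", "C", "T"), V = c("A", "C", "G"),
                   N = c("A", "C", "G", "T"))

# resolve IUPAC ambiguity codes uniformly at random (uses the current RNG)
resolve_iupac <- function(motif) {
  ch <- strsplit(motif, "")[[1]]
  paste(vapply(ch, function(c) {
    s <- iupac_sets[[c]]
    if (is.null(s)) stop("unknown IUPAC code: ", c)
    if (length(s) == 1) s else sample(s, 1)
  }, character(1)), collapse = "")
}
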