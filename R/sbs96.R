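#' SBS-96 channel conventions
#'
#' Single-base substitutions are summarised on the standard pyrimidine-centric
#' 96-channel alphabet: six substitution classes (C>A, C>G, C>T, T>A, T>C,
#' T>G) crossed with the 16 trinucleotide contexts of the mutated base.
#' Mutations reported with a purine reference (G or A) are reverse-complemented
#' onto the pyrimidine strand, so the 192 possible (ref, alt, context)
#' combinations collapse two-to-one onto 96 channels.
#'
#' @return `sbs96_labels()` returns the 96 channel labels (e.g. `"A[C>A]A"`)
#'   in canonical order: substitution classes in the order above, contexts
#'   ordered by 5' then 3' base (A, C, G, T).
#' @export
#' @examples
#' sbs96_labels()[1:4]
sbs96_labels <- function() {
  bases <- c("A", "C", "G", "T")
  subs <- c("C>A", "C>G", "C>T", "T>A", "T>C", "T>G")
  unlist(lapply(subs, function(s) {
    ref <- substr(s, 1, 1)
    as.vector(t(outer(bases, bases, function(p5, p3) {
      paste0(p5, "[", s, "]", p3)
    })))
  }))
}

REVCOMP <- c(A = "T", C = "G", G = "C", T = "A")

#' Reverse complement of a DNA string vector
#'
#' @param x character vector of A/C/G/T strings.
#' @return character vector of reverse complements.
#' @export
revcomp <- function(x) {
  vapply(strsplit(toupper(x), ""), function(b) {
    bad <- !b %in% names(REVCOMP)
    if (any(bad)) stop("ambiguous base in sequence: ", paste(b[bad], collapse = ","))
    paste(rev(unname(REVCOMP[b])), collapse = "")
  }, character(1))
}

#' Map a substitution to its SBS-96 channel
#'
#' Purine-reference mutations are reverse-complemented onto the
#' pyrimidine-centric channel set, so `(G, T, "TGT")` and `(C, A, "ACA")`
#' land on the same channel.
#'
#' @param ref,alt single reference / alternate bases (vectorised).
#' @param context 3-base reference-strand context centred on `ref`.
#' @return integer channel index in 1..96, named with the channel label.
#' @export
#' @examples
#' sbs96_channel("C", "A", "ACA")
#' sbs96_channel("G", "T", "TGT") # same channel by strand symmetry
sbs96_channel <- function(ref, alt, context) {
  ref <- toupper(ref); alt <- toupper(alt); context <- toupper(context)
  n <- length(ref)
  stopifnot(length(alt) == n, length(context) == n)
  ok_base <- function(b) b %in% c("A", "C", "G", "T")
  if (!all(ok_base(ref)) || !all(ok_base(alt)) ||
      !all(grepl("^[ACGT]{3}$", context))) {
    stop("ambiguous or invalid base (only A/C/G/T allowed)")
  }
  if (any(ref == alt)) stop("ref and alt must differ")
  if (any(substr(context, 2, 2) != ref)) {
    stop("context centre base must equal ref")
  }
  is_purine <- ref %in% c("A", "G")
  ref[is_purine] <- unname(REVCOMP[ref[is_purine]])
  alt[is_purine] <- unname(REVCOMP[alt[is_purine]])
  context[is_purine] <- revcomp(context[is_purine])
  labels <- paste0(
    substr(context, 1, 1), "[", ref, ">", alt, "]", substr(context, 3, 3)
  )
  idx <- match(labels, sbs96_labels())
  names(idx) <- labels
  idx
}
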