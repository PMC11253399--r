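#' Synthetic SBS signature reference catalogue
#'
#' The real COSMIC SBS catalogue is distributed by COSMIC and is not bundled
#' here. For simulation and testing this constructor builds a *synthetic*
#' stand-in: deterministic 96-channel profiles whose characteristic peaks are
#' inspired by the well-known shapes (e.g. APOBEC C>T / C>G at TpC, the
#' oesophageal-hallmark T>G at NpTpT, platinum C>A / C>T at CpC), plus a
#' signature-specific low-amplitude background so every column is linearly
#' independent. The profiles are *not* the COSMIC probabilities; analyses of
#' real data should load the genuine catalogue with
#' [read_signature_matrix()].
#'
#' @param signatures character vector of signature ids to build; defaults to
#'   the treatment-naive analysis set plus the platinum pair
#'   (`"SBS31"`, `"SBS35"`).
#' @return a `signature_matrix` (96 x S, columns sum to 1).
#' @seealso [oac_signature_set()] for the default id set.
#' @export
#' @examples
#' m <- sbs_reference()
#' colSums(m)[1:3]
sbs_reference <- function(signatures = c(oac_signature_set(), "SBS31", "SBS35")) {
  defs <- sbs_reference_defs()
  unknown <- setdiff(signatures, names(defs))
  if (length(unknown) > 0) {
    stop("no synthetic profile defined for: ", paste(unknown, collapse = ", "))
  }
  labs <- sbs96_labels()
  probs <- vapply(signatures, function(sig) {
    build_profile(defs[[sig]], which(names(defs) == sig))
  }, numeric(96))
  rownames(probs) <- labs
  as_signature_matrix(probs)
}

#' Default signature id set for treatment-naive analyses
#'
#' The SBS signatures retained for this tumour type after cohort-level
#' screening (>= 10% exposure in at least one sample): clock-like (SBS1,
#' SBS5, SBS40), APOBEC (SBS2, SBS13), HR-deficiency-like (SBS3),
#' mismatch-repair (SBS20, SBS26, SBS44), oxidative damage (SBS18, SBS36),
#' the gastric-reflux-associated hallmark pair (SBS17a, SBS17b), and broad
#' signatures SBS8, SBS39, SBS93. Platinum signatures SBS31/SBS35 are *not*
#' part of this set; they are appended only for pre-/post-treatment analyses.
#'
#' @return character vector of signature ids.
#' @export
oac_signature_set <- function() {
  c("SBS1", "SBS2", "SBS3", "SBS5", "SBS8", "SBS13", "SBS17a", "SBS17b",
    "SBS18", "SBS20", "SBS26", "SBS36", "SBS39", "SBS40", "SBS44", "SBS93")
}

#' Signature grouping used for reporting
#'
#' @return named list of signature id sets: `APOBEC` (SBS2 + SBS13) and
#'   `MMR/MSI` (SBS20 + SBS26 + SBS44).
#' @export
signature_groups <- function() {
  list(`APOBEC` = c("SBS2", "SBS13"),
       `MMR/MSI` = c("SBS20", "SBS26", "SBS44"))
}

# Peak definitions: sub is one of the six pyrimidine substitution classes;
# p5/p3 are allowed flanking bases ("N" = any). peak_mass is the probability
# mass placed on the peaks; the rest goes to a signature-specific smooth
# background ripple.
sbs_reference_defs <- function() {
  pk <- function(sub, p5, p3, w = 1) list(sub = sub, p5 = p5, p3 = p3, w = w)
  list(
    SBS1   = list(mass = 0.75, peaks = list(pk("C>T", "N", "G"))),
    SBS2   = list(mass = 0.80, peaks = list(pk("C>T", "T", "N"))),
    SBS3   = list(mass = 0.00, peaks = list()),
    SBS5   = list(mass = 0.45, peaks = list(pk("T>C", "N", "N"))),
    SBS8   = list(mass = 0.55, peaks = list(pk("C>A", "N", "N"))),
    SBS13  = list(mass = 0.80, peaks = list(pk("C>G", "T", "N"))),
    SBS17a = list(mass = 0.75, peaks = list(pk("T>C", "N", "T"))),
    SBS17b = list(mass = 0.80, peaks = list(pk("T>G", "C", "T", 3),
                                            pk("T>G", "A", "T", 1),
                                            pk("T>G", "T", "T", 1))),
    SBS18  = list(mass = 0.70, peaks = list(pk("C>A", "N", "A"))),
    SBS20  = list(mass = 0.70, peaks = list(pk("C>T", "G", "N", 2),
                                            pk("T>C", "C", "N", 1))),
    SBS26  = list(mass = 0.70, peaks = list(pk("T>C", "A", "N"))),
    SBS36  = list(mass = 0.70, peaks = list(pk("C>A", "N", "G"))),
    SBS39  = list(mass = 0.60, peaks = list(pk("C>G", "N", "N"))),
    SBS40  = list(mass = 0.00, peaks = list()),
    SBS44  = list(mass = 0.70, peaks = list(pk("C>T", "A", "N"))),
    SBS93  = list(mass = 0.60, peaks = list(pk("T>A", "N", "N"))),
    SBS31  = list(mass = 0.75, peaks = list(pk("C>T", "C", "N"))),
    SBS35  = list(mass = 0.75, peaks = list(pk("C>A", "C", "N", 2),
                                            pk("C>T", "C", "N", 1)))
  )
}

build_profile <- function(def, idx) {
  labs <- sbs96_labels()
  j <- seq_len(96) - 1
  # background: strictly positive smooth ripple, unique per signature
  freq <- 1 + (idx %% 5)
  phase <- idx / 7
  bg <- 1 + 0.4 * sin(2 * pi * (freq * j / 96 + phase))
  bg <- bg / sum(bg)
  peak <- numeric(96)
  for (p in def$peaks) {
    sel <- grepl(paste0("\\[", p$sub, "\\]"), labs, fixed = FALSE)
    if (p$p5 != "N") sel <- sel & substr(labs, 1, 1) == p$p5
    if (p$p3 != "N") sel <- sel & substr(labs, 7, 7) == p$p3
    peak[sel] <- peak[sel] + p$w / sum(sel)
  }
  if (sum(peak) > 0) peak <- peak / sum(peak)
  prof <- def$mass * peak + (1 - def$mass) * bg
  prof / sum(prof)
}
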