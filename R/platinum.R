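#' Platinum-signature enrichment odds ratio
#'
#' Platinum-based chemotherapy leaves C>A substitutions in a CpC context.
#' This statistic compares the odds that a mutated cytosine sits in a CpC
#' context against the background odds of CpC among all reference cytosines
#' in windows (default 41 bases) centred on each mutated base.
#'
#' Eligible mutations are C>A on the reference strand and G>T (the same
#' event read from the opposite strand, counted after reverse
#' complementation). "CpC context" means the mutated cytosine has a cytosine
#' as its immediate 5' neighbour on the C-containing strand; set
#' `context_side = "3p"` for the 3'-neighbour reading of the convention.
#' Background counts pool the mutation-centred windows with multiplicity,
#' counting every reference C (and every G, as a reverse-strand C) as CpC or
#' not by the same rule. When any cell of the 2x2 table is zero, 0.5 is
#' added to every cell (Haldane correction) and the result is flagged.
#'
#' @param records mutation tibble for one mutation population.
#' @param genome named character vector from [read_genome()].
#' @param window odd window width in bases (default 41).
#' @param context_side `"5p"` (default) or `"3p"` neighbour convention.
#' @return a one-row tibble: `odds_ratio`, the four table cells
#'   (`mut_cpc`, `mut_noncpc`, `bg_cpc`, `bg_noncpc`), `n_eligible`,
#'   `haldane` (correction applied) and `flagged_undefined` (no eligible
#'   mutations; `odds_ratio` is `NA`).
#' @export
platinum_enrichment <- function(records, genome, window = 41,
                                context_side = c("5p", "3p")) {
  context_side <- match.arg(context_side)
  stopifnot(window %% 2 == 1)
  flank <- (window - 1) %/% 2
  undefined <- tibble::tibble(
    odds_ratio = NA_real_, mut_cpc = 0L, mut_noncpc = 0L,
    bg_cpc = 0L, bg_noncpc = 0L, n_eligible = 0L,
    haldane = FALSE, flagged_undefined = TRUE
  )
  if (nrow(records) == 0) return(undefined)
  ref <- toupper(records$ref); alt <- toupper(records$alt)
  eligible <- (ref == "C" & alt == "A") | (ref == "G" & alt == "T")
  rec <- records[eligible, , drop = FALSE]
  if (nrow(rec) == 0) return(undefined)
  chrom <- normalise_chrom(rec$chrom, genome)

  mut_cpc <- 0L; mut_non <- 0L; bg_cpc <- 0L; bg_non <- 0L; n_used <- 0L
  for (i in seq_len(nrow(rec))) {
    contig <- genome[[chrom[i]]]
    p <- rec$pos[i]
    if (p - flank < 1 || p + flank > nchar(contig)) next  # window off contig
    win <- substr(contig, p - flank, p + flank)
    is_g <- toupper(rec$ref[i]) == "G"
    neigh <- cpc_neighbour(contig, p, is_g, context_side)
    if (is.na(neigh)) next
    n_used <- n_used + 1L
    if (neigh) mut_cpc <- mut_cpc + 1L else mut_non <- mut_non + 1L
    bg <- window_cpc_counts(win, context_side)
    bg_cpc <- bg_cpc + bg[["cpc"]]
    bg_non <- bg_non + bg[["noncpc"]]
  }
  if (n_used == 0) return(undefined)
  cells <- c(mut_cpc, mut_non, bg_cpc, bg_non)
  haldane <- any(cells == 0)
  adj <- if (haldane) cells + 0.5 else cells
  or <- (adj[1] / adj[2]) / (adj[3] / adj[4])
  tibble::tibble(
    odds_ratio = or, mut_cpc = mut_cpc, mut_noncpc = mut_non,
    bg_cpc = bg_cpc, bg_noncpc = bg_non, n_eligible = n_used,
    haldane = haldane, flagged_undefined = FALSE
  )
}

# Is the mutated C (possibly on the reverse strand, is_g = TRUE) in CpC
# context? 5' neighbour on the C strand; NA if the neighbour falls off the
# contig.
cpc_neighbour <- function(contig, pos, is_g, context_side) {
  # for a forward C, 5' neighbour is pos-1; for a reverse-strand C (ref G),
  # its 5' neighbour on that strand is the complement of forward pos+1
  offset <- if (context_side == "5p") -1L else 1L
  if (is_g) offset <- -offset
  q <- pos + offset
  if (q < 1 || q > nchar(contig)) return(NA)
  b <- substr(contig, q, q)
  if (is_g) b == "G" else b == "C"
}

# Count reference C positions (both strands: C forward, G as reverse-strand
# C) inside one window, split into CpC vs non-CpC context.
window_cpc_counts <- function(win, context_side) {
  b <- strsplit(win, "")[[1]]
  n <- length(b)
  cpc <- 0L; noncpc <- 0L
  for (j in seq_len(n)) {
    if (b[j] == "C") {
      q <- if (context_side == "5p") j - 1L else j + 1L
      if (q < 1 || q > n) next
      if (b[q] == "C") cpc <- cpc + 1L else noncpc <- noncpc + 1L
    } else if (b[j] == "G") {
      q <- if (context_side == "5p") j + 1L else j - 1L
      if (q < 1 || q > n) next
      if (b[q] == "G") cpc <- cpc + 1L else noncpc <- noncpc + 1L
    }
  }
  c(cpc = cpc, noncpc = noncpc)
}
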