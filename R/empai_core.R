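# emPAI core: in-silico tryptic digestion, observable-peptide counting under a
# monoisotopic mass window, and the exponentially modified protein abundance
# index with cell-number normalization.

# Monoisotopic residue masses (Da) for the 20 standard amino acids, and the
# mass of water added per peptide. Values match the standard tables used in
# MS software to 5 decimals.
MONO_MASS <- c(
  G = 57.02146, A = 71.03711, S = 87.03203, P = 97.05276, V = 99.06841,
  T = 101.04768, C = 103.00919, L = 113.08406, I = 113.08406, N = 114.04293,
  D = 115.02694, Q = 128.05858, K = 128.09496, E = 129.04259, M = 131.04049,
  H = 137.05891, F = 147.06841, R = 156.10111, Y = 163.06333, W = 186.07931
)
WATER_MONO <- 18.01056

#' Digestion rule for in-silico proteolysis
#'
#' Trypsin cleaves C-terminal to lysine (K) or arginine (R) except when the
#' next residue is proline (P). The observable window bounds the peptide
#' monoisotopic mass range the instrument is assumed to detect.
#'
#' @param missed_cleavages non-negative integer, at most 2; merged runs of up
#'   to `missed_cleavages + 1` adjacent fragments are also emitted.
#' @param observable_window numeric length-2, monoisotopic mass interval in Da.
#' @return a `digestion_rule` object.
#' @export
digestion_rule <- function(missed_cleavages = 0,
                           observable_window = c(800, 4500)) {
  if (missed_cleavages < 0 || missed_cleavages > 2) {
    stop("missed_cleavages must be between 0 and 2")
  }
  if (length(observable_window) != 2 ||
      observable_window[1] >= observable_window[2]) {
    stop("observable_window must be an increasing length-2 interval")
  }
  structure(list(missed_cleavages = as.integer(missed_cleavages),
                 observable_window = as.numeric(observable_window)),
            class = "digestion_rule")
}

#' In-silico tryptic digestion
#'
#' Cleaves strictly after K or R unless the following residue is P. With `m`
#' allowed missed cleavages, every merged run of up to `m + 1` adjacent
#' fragments is additionally emitted, in order of start position.
#'
#' @param sequence amino-acid string (one-letter codes; `X` tolerated, handled
#'   downstream).
#' @param rule a [digestion_rule()].
#' @return character vector of peptides; at 0 missed cleavages their
#'   concatenation reconstructs the input.
#' @examples
#' tryptic_digest("AKRP")   # no cleavage after R: next residue is P
#' tryptic_digest("AKCK", digestion_rule(missed_cleavages = 1))
#' @export
tryptic_digest <- function(sequence, rule = digestion_rule()) {
  if (!nzchar(sequence)) stop("sequence must be non-empty")
  sequence <- toupper(sequence)
  residues <- strsplit(sequence, "")[[1]]
  bad <- !residues %in% c(names(MONO_MASS), "X")
  if (any(bad)) {
    stop("invalid residue(s) in sequence: ",
         paste(unique(residues[bad]), collapse = ", "))
  }
  base <- strsplit(sequence, "(?<=[KR])(?!P)", perl = TRUE)[[1]]
  m <- rule$missed_cleavages
  if (m == 0L || length(base) == 1L) return(base)
  out <- base
  for (k in seq_len(m)) {
    n <- length(base) - k
    if (n < 1L) break
    merged <- vapply(seq_len(n), function(i) {
      paste(base[i:(i + k)], collapse = "")
    }, character(1))
    out <- c(out, merged)
  }
  out
}

#' Monoisotopic peptide mass
#'
#' Sum of residue monoisotopic masses plus one water. Peptides containing a
#' residue outside the 20 standard codes return `NA`.
#'
#' @param peptides character vector of peptide sequences.
#' @return numeric vector of masses in Da (`NA` for non-standard peptides).
#' @export
peptide_mass <- function(peptides) {
  vapply(peptides, function(p) {
    res <- strsplit(p, "")[[1]]
    if (any(!res %in% names(MONO_MASS))) return(NA_real_)
    sum(MONO_MASS[res]) + WATER_MONO
  }, numeric(1), USE.NAMES = FALSE)
}

#' Observable peptides of a digest
#'
#' The distinct peptides whose monoisotopic mass falls inside the rule's
#' observable window. Peptides containing non-standard residues are dropped
#' with a warning.
#'
#' @param peptides character vector from [tryptic_digest()].
#' @param rule a [digestion_rule()].
#' @return character vector of distinct observable peptide sequences.
#' @export
observable_peptides <- function(peptides, rule = digestion_rule()) {
  peptides <- unique(peptides)
  mass <- peptide_mass(peptides)
  if (anyNA(mass)) {
    cf_log("WARN", sum(is.na(mass)),
           " peptide(s) with non-standard residues dropped from observable set")
  }
  w <- rule$observable_window
  keep <- !is.na(mass) & mass >= w[1] & mass <= w[2]
  peptides[keep]
}

#' @rdname observable_peptides
#' @return `count_observable()` returns the number of distinct observable
#'   peptides.
#' @export
count_observable <- function(peptides, rule = digestion_rule()) {
  length(observable_peptides(peptides, rule))
}

#' emPAI: exponentially modified protein abundance index
#'
#' `empai = 10^(n_observed / n_observable) - 1`, where `n_observed` is the
#' number of distinct identified peptides of the protein and `n_observable`
#' the number of distinct in-silico peptides within the instrument's mass
#' range. The index is approximately proportional to protein amount.
#'
#' @param n_observed count of distinct observed peptides, `0 <= n_observed <=
#'   n_observable`.
#' @param n_observable count of observable peptides, `> 0`.
#' @return dimensionless index in `[0, 9]`.
#' @examples
#' compute_empai(3, 10)  # 10^0.3 - 1
#' @export
compute_empai <- function(n_observed, n_observable) {
  if (any(n_observable <= 0)) {
    stop("n_observable must be positive (protein has no observable peptides)")
  }
  if (any(n_observed < 0)) stop("n_observed must be non-negative")
  if (any(n_observed > n_observable)) {
    stop("n_observed exceeds n_observable: check the digestion rule ",
         "and observable window against the identification table")
  }
  10^(n_observed / n_observable) - 1
}

#' Cell-number normalization of emPAI
#'
#' Rescales an emPAI value measured on membranes from `cells_loaded` cells to
#' a common reference cell number, linearly: the index is treated as
#' proportional to protein amount, so loading half the cells halves it.
#'
#' @param empai emPAI value(s).
#' @param cells_loaded number of cells the analyzed membranes came from.
#' @param cells_reference the common reference cell number.
#' @return rescaled emPAI.
#' @export
normalize_to_cells <- function(empai, cells_loaded, cells_reference) {
  if (cells_loaded <= 0 || cells_reference <= 0) {
    stop("cell counts must be positive")
  }
  empai * cells_reference / cells_loaded
}

#' Build the protein-by-fraction emPAI table
#'
#' For each protein and fraction, counts the distinct identified peptides that
#' match (string equality) a member of the protein's observable digest,
#' computes emPAI, and normalizes to a common cell number. Proteins absent
#' from a fraction carry emPAI 0 there. Identified peptides not found in the
#' protein's digest are excluded from the count with a logged warning;
#' peptides in the digest but outside the observable window are likewise not
#' counted, preserving `n_observed <= n_observable`.
#'
#' @param rows identification table, as from [read_id_table()].
#' @param proteome protein data.frame, as from [read_fasta()].
#' @param rule a [digestion_rule()].
#' @param norms named list mapping fraction id to the number of cells loaded
#'   for that fraction's run (single number = same for all fractions).
#' @param cells_reference the common reference cell number.
#' @param fractions fraction identifiers defining the table columns.
#' @return a data.frame with `protein_id` plus one emPAI column per fraction,
#'   and attributes `n_observable` (named counts) and `unmatched_peptides`.
#' @export
build_fraction_table <- function(rows, proteome, rule = digestion_rule(),
                                 norms = NULL, cells_reference = 5e4,
                                 fractions = FRACTIONS) {
  unknown <- setdiff(unique(rows$protein_id), proteome$protein_id)
  if (length(unknown)) {
    stop("identification table references protein(s) absent from the ",
         "proteome: ", paste(head(unknown, 5), collapse = ", "))
  }
  if (is.null(norms)) norms <- setNames(rep(cells_reference, length(fractions)),
                                        fractions)
  if (length(norms) == 1L && is.null(names(norms))) {
    norms <- setNames(rep(norms, length(fractions)), fractions)
  }
  obs_sets <- lapply(proteome$sequence, function(s) {
    observable_peptides(tryptic_digest(s, rule), rule)
  })
  names(obs_sets) <- proteome$protein_id
  digests <- lapply(proteome$sequence, function(s) tryptic_digest(s, rule))
  names(digests) <- proteome$protein_id

  tab <- matrix(0, nrow = nrow(proteome), ncol = length(fractions),
                dimnames = list(proteome$protein_id, fractions))
  n_unmatched <- 0L
  if (nrow(rows) > 0L) {
    # pool replicates: distinct peptides per (fraction, protein)
    key <- unique(rows[, c("fraction_id", "protein_id", "peptide_sequence")])
    split_fp <- split(key$peptide_sequence,
                      list(key$fraction_id, key$protein_id), drop = TRUE)
    for (nm in names(split_fp)) {
      parts <- strsplit(nm, ".", fixed = TRUE)[[1]]
      frac <- parts[1]
      pid <- paste(parts[-1], collapse = ".")
      peps <- unique(split_fp[[nm]])
      in_digest <- peps %in% digests[[pid]]
      if (any(!in_digest)) n_unmatched <- n_unmatched + sum(!in_digest)
      n_obs <- sum(peps %in% obs_sets[[pid]])
      n_obsbl <- length(obs_sets[[pid]])
      if (n_obsbl == 0L) {
        cf_log("WARN", "protein ", pid, " has no observable peptides; ",
               "emPAI left at 0")
        next
      }
      empai <- compute_empai(n_obs, n_obsbl)
      tab[pid, frac] <- normalize_to_cells(empai, norms[[frac]],
                                           cells_reference)
    }
  }
  if (n_unmatched > 0L) {
    cf_log("WARN", n_unmatched, " identified peptide(s) not found in their ",
           "protein's digest; excluded from observed counts")
  }
  out <- data.frame(protein_id = rownames(tab), tab, row.names = NULL,
                    stringsAsFactors = FALSE)
  attr(out, "n_observable") <- vapply(obs_sets, length, integer(1))
  attr(out, "unmatched_peptides") <- n_unmatched
  out
}
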