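# Seeded generators producing every input the pipeline consumes, with the
# statistical structure the analysis assumes: a compartment-resolved ground
# truth proteome, a fraction-mixing process with marker-like recoveries, an
# abundance-dependent peptide-detection process under which emPAI is
# approximately proportional to amount, pigment bleach series, and linear
# calibration series.

LOCALIZATION_CLASSES <- c("COS_specific", "CIS_resident", "ROS_shared",
                          "RIS_resident", "shared_OS", "blood_contaminant")
COMPARTMENTS <- c("OS", "mito_inner", "mito_outer", "IS_plasma", "ER", "blood")
IS_COMPARTMENTS <- c("mito_inner", "mito_outer", "IS_plasma", "ER")

# Run code under a fixed seed without disturbing the caller's RNG stream.
with_seed <- function(seed, code) {
  old <- if (exists(".Random.seed", envir = globalenv())) {
    get(".Random.seed", envir = globalenv())
  }
  on.exit({
    if (is.null(old)) {
      if (exists(".Random.seed", envir = globalenv())) {
        rm(".Random.seed", envir = globalenv())
      }
    } else {
      assign(".Random.seed", old, envir = globalenv())
    }
  })
  set.seed(seed)
  force(code)
}

#' Default fraction-mixing matrix
#'
#' Recovery fractions of each compartment's membranes into each gradient
#' fraction, transcribed from a marker-recovery experiment on carp
#' photoreceptors (visual pigment for OS membranes; F1 ATPase beta, TOM20,
#' Na+/K+ ATPase alpha and calnexin for the inner-segment compartments). The
#' `blood` column is a modeling addition: red-blood-cell membranes
#' contaminate both purified-cell preparations in small amounts and, being
#' light, are taken to co-migrate mostly with the upper (OS-rich) fractions.
#'
#' @return a fractions-by-compartments numeric matrix of recoveries in
#'   `[0, 1]`.
#' @export
default_mixing_matrix <- function() {
  m <- rbind(
    ROS = c(OS = 0.862, mito_inner = 0.000, mito_outer = 0.091,
            IS_plasma = 0.657, ER = 0.265, blood = 0.80),
    RIS = c(OS = 0.009, mito_inner = 0.848, mito_outer = 0.425,
            IS_plasma = 0.402, ER = 0.099, blood = 0.05),
    COS = c(OS = 0.545, mito_inner = 0.035, mito_outer = 0.069,
            IS_plasma = 0.490, ER = 0.355, blood = 0.80),
    CIS = c(OS = 0.035, mito_inner = 0.546, mito_outer = 0.582,
            IS_plasma = 0.109, ER = 0.384, blood = 0.05)
  )
  m
}

#' Simulate a ground-truth proteome
#'
#' Draws protein sequences (length 80-600, ~12% combined K/R so tryptic
#' digests are peptide-rich), assigns each protein a localization class and a
#' log-normal abundance. Classes map to compartments as follows:
#' `COS_specific` = cone OS only; `CIS_resident` = one cone inner-segment
#' compartment; `ROS_shared` = the OS of both rods and cones (shared
#' phototransduction machinery, removed downstream by the ROS rule);
#' `RIS_resident` = one rod inner-segment compartment; `shared_OS` = both the
#' OS and an inner-segment compartment of the cone; `blood_contaminant` =
#' red-blood-cell membranes present in both purified-cell preparations.
#'
#' @param n_proteins number of proteins, >= 1.
#' @param class_proportions named numeric vector over the six localization
#'   classes, summing to 1.
#' @param abundance_lognormal `c(meanlog, sdlog)` of the abundance
#'   distribution (AU).
#' @param seed integer seed; fixed seed gives identical proteomes.
#' @return a data.frame (class `ground_truth_proteome`) with columns
#'   `protein_id`, `description`, `sequence`, `localization_class`,
#'   `is_compartment` (NA unless the class occupies an inner-segment
#'   compartment) and `abundance`.
#' @export
simulate_proteome <- function(n_proteins,
                              class_proportions = c(
                                COS_specific = 0.07, CIS_resident = 0.40,
                                ROS_shared = 0.25, RIS_resident = 0.20,
                                shared_OS = 0.05, blood_contaminant = 0.03),
                              abundance_lognormal = c(0, 1),
                              seed = 1) {
  if (n_proteins < 1) stop("n_proteins must be at least 1")
  if (!all(names(class_proportions) %in% LOCALIZATION_CLASSES)) {
    stop("unknown localization class(es): ",
         paste(setdiff(names(class_proportions), LOCALIZATION_CLASSES),
               collapse = ", "))
  }
  if (abs(sum(class_proportions) - 1) > 1e-9) {
    stop("class_proportions must sum to 1")
  }
  with_seed(seed, {
    # residue frequencies: K+R at 12%, remaining mass spread over the others
    other <- setdiff(STANDARD_AA, c("K", "R"))
    probs <- c(setNames(rep(0.88 / length(other), length(other)), other),
               K = 0.06, R = 0.06)
    lens <- sample(80:600, n_proteins, replace = TRUE)
    seqs <- vapply(lens, function(L) {
      paste(sample(names(probs), L, replace = TRUE, prob = probs),
            collapse = "")
    }, character(1))
    cls <- sample(names(class_proportions), n_proteins, replace = TRUE,
                  prob = class_proportions)
    # Inner-segment residents live in organellar membranes (the ellipsoid is
    # dominated by mitochondria, with some ER); the plasma membrane is
    # continuous between inner and outer segment, so it cannot host a
    # compartment-confined resident class and is left to the marker
    # bookkeeping only.
    isc <- ifelse(cls %in% c("CIS_resident", "RIS_resident", "shared_OS"),
                  sample(c("mito_inner", "mito_outer", "ER"), n_proteins,
                         replace = TRUE, prob = c(0.5, 0.3, 0.2)),
                  NA_character_)
    abund <- rlnorm(n_proteins, abundance_lognormal[1], abundance_lognormal[2])
    out <- data.frame(
      protein_id = sprintf("SYN%04d", seq_len(n_proteins)),
      description = paste0("synthetic ", cls, " protein"),
      sequence = seqs,
      localization_class = cls,
      is_compartment = isc,
      abundance = abund,
      stringsAsFactors = FALSE
    )
    class(out) <- c("ground_truth_proteome", class(out))
    out
  })
}

#' Detection model for observable peptides
#'
#' Each observable peptide of a protein present at amount `a` in a fraction
#' is detected independently with probability `p(a) = 1 - exp(-a / kappa)`:
#' the simplest saturating model under which the expected observed/observable
#' ratio, and hence emPAI, grows roughly in proportion to amount before
#' saturating.
#'
#' @param kappa abundance scale of detection (AU); default 1.5 puts the
#'   median detection ratio near 0.3 for a unit-median-abundance proteome
#'   passed through the default cone OS recovery.
#' @return a `detection_model` object.
#' @export
detection_model <- function(kappa = 1.5) {
  if (kappa <= 0) stop("kappa must be positive")
  structure(list(kappa = kappa), class = "detection_model")
}

# Per-fraction protein amount: sum over compartments of
# abundance x recovery x compartment volume weight. Rod fractions read only
# the classes present in the rod preparation.
.true_fraction_amounts <- function(proteome, mixing, geometry) {
  vw <- setNames(rep(1, length(COMPARTMENTS)), COMPARTMENTS)
  vw[IS_COMPARTMENTS] <- geometry$is_os_volume_ratio
  occupancy <- function(cls, isc) {
    # named compartment amounts (multipliers of abundance) per cell type
    cone <- setNames(numeric(length(COMPARTMENTS)), COMPARTMENTS)
    rod <- cone
    switch(cls,
      COS_specific = { cone["OS"] <- 1 },
      CIS_resident = { cone[isc] <- 1 },
      ROS_shared = { cone["OS"] <- 1; rod["OS"] <- 1 },
      RIS_resident = { rod[isc] <- 1 },
      shared_OS = { cone["OS"] <- 1; cone[isc] <- 1 },
      blood_contaminant = { cone["blood"] <- 1; rod["blood"] <- 1 }
    )
    list(cone = cone, rod = rod)
  }
  amounts <- matrix(0, nrow = nrow(proteome), ncol = nrow(mixing),
                    dimnames = list(proteome$protein_id, rownames(mixing)))
  for (i in seq_len(nrow(proteome))) {
    occ <- occupancy(proteome$localization_class[i],
                     proteome$is_compartment[i])
    a <- proteome$abundance[i]
    for (f in rownames(mixing)) {
      cell <- if (f %in% c("ROS", "RIS")) occ$rod else occ$cone
      amounts[i, f] <- a * sum(cell * mixing[f, COMPARTMENTS] *
                                 vw[COMPARTMENTS])
    }
  }
  amounts
}

#' Simulate peptide identification tables
#'
#' Computes each protein's amount in each fraction from the mixing matrix and
#' compartment volume weights, then detects each observable peptide
#' independently with the detection model's probability. Output rows conform
#' to the identification-table schema consumed by [build_fraction_table()].
#'
#' @param proteome a [simulate_proteome()] result.
#' @param mixing fractions-by-compartments recovery matrix.
#' @param detection a [detection_model()].
#' @param geometry a [geometry_config()].
#' @param rule a [digestion_rule()].
#' @param n_replicates number of independent experiments; peptides observed
#'   in any replicate are pooled by union downstream. Default 2, matching the
#'   two-independent-experiment design the pipeline emulates.
#' @param seed integer seed.
#' @return a data.frame with columns `fraction_id`, `protein_id`,
#'   `peptide_sequence`, `replicate_id`, and attribute `true_amounts`
#'   (protein-by-fraction matrix of ground-truth amounts).
#' @export
simulate_fraction_tables <- function(proteome, mixing = default_mixing_matrix(),
                                     detection = detection_model(),
                                     geometry = geometry_config(),
                                     rule = digestion_rule(),
                                     n_replicates = 2, seed = 1) {
  amounts <- .true_fraction_amounts(proteome, mixing, geometry)
  obs_sets <- lapply(proteome$sequence, function(s) {
    observable_peptides(tryptic_digest(s, rule), rule)
  })
  with_seed(seed, {
    rows <- vector("list", nrow(proteome) * ncol(amounts) * n_replicates)
    k <- 0L
    for (i in seq_len(nrow(proteome))) {
      peps <- obs_sets[[i]]
      if (length(peps) == 0L) next
      for (f in colnames(amounts)) {
        p <- 1 - exp(-amounts[i, f] / detection$kappa)
        if (p <= 0) next
        for (r in seq_len(n_replicates)) {
          hit <- runif(length(peps)) < p
          if (!any(hit)) next
          k <- k + 1L
          rows[[k]] <- data.frame(
            fraction_id = f, protein_id = proteome$protein_id[i],
            peptide_sequence = peps[hit], replicate_id = r,
            stringsAsFactors = FALSE)
        }
      }
    }
    out <- if (k > 0L) do.call(rbind, rows[seq_len(k)]) else {
      data.frame(fraction_id = character(), protein_id = character(),
                 peptide_sequence = character(), replicate_id = integer(),
                 stringsAsFactors = FALSE)
    }
    rownames(out) <- NULL
    attr(out, "true_amounts") <- amounts
    out
  })
}

#' Simulate a sequential-bleach spectrum series
#'
#' Curve 1 is the composed pre-bleach spectrum; each subsequent curve removes
#' `completeness_k` of the targeted pigment's contribution. Independent
#' Gaussian noise of standard deviation `noise_sigma` is added to every point
#' of every curve.
#'
#' @param amounts named pigment contents (AU).
#' @param templates list of [pigment_template()] objects.
#' @param steps list of [bleach_step()]; default bleaches each pigment in
#'   `names(amounts)` order, completely.
#' @param noise_sigma absorbance noise standard deviation (AU).
#' @param baseline flat absorbance offset.
#' @param grid wavelength grid, nm.
#' @param seed integer seed.
#' @return a [spectrum_series()] with `length(steps) + 1` curves.
#' @export
simulate_bleach_series <- function(amounts, templates, steps = NULL,
                                   noise_sigma = 0, baseline = 0,
                                   grid = seq(350, 750, by = 1), seed = 1) {
  if (any(amounts < 0)) stop("pigment amounts must be non-negative")
  if (is.null(steps)) {
    steps <- lapply(seq_along(amounts), function(k) {
      bleach_step(k, names(amounts)[k])
    })
  }
  tnames <- vapply(templates, `[[`, character(1), "name")
  cur <- compose_spectrum(amounts, templates, baseline, grid)
  curves <- matrix(0, nrow = length(grid), ncol = length(steps) + 1)
  curves[, 1] <- cur
  for (k in seq_along(steps)) {
    step <- steps[[k]]
    tpl <- templates[[match(step$pigment_targeted, tnames)]]
    cur <- cur - step$completeness * amounts[[step$pigment_targeted]] *
      template_absorbance(grid, tpl)
    curves[, k + 1] <- cur
  }
  if (noise_sigma > 0) {
    curves <- with_seed(seed, {
      curves + matrix(rnorm(length(curves), 0, noise_sigma),
                      nrow = nrow(curves))
    })
  }
  labels <- c("pre_bleach",
              vapply(steps, function(s) {
                paste0("after_", s$pigment_targeted)
              }, character(1)))
  spectrum_series(grid, curves, labels)
}

#' Simulate a linear calibration series
#'
#' Evenly spaced standard amounts with signals on a line plus Gaussian noise.
#'
#' @param slope signal units per standard unit.
#' @param intercept signal at zero amount.
#' @param noise_sigma signal noise standard deviation.
#' @param n_points number of standards, >= 2.
#' @param max_amount largest standard amount.
#' @param seed integer seed.
#' @return a data.frame with `standard_amount` and `signal`.
#' @export
simulate_calibration <- function(slope, intercept = 0, noise_sigma = 0,
                                 n_points = 5, max_amount = 10, seed = 1) {
  if (n_points < 2) stop("need at least 2 calibration points")
  amounts <- seq(max_amount / n_points, max_amount, length.out = n_points)
  signals <- slope * amounts + intercept
  if (noise_sigma > 0) {
    signals <- with_seed(seed, signals + rnorm(n_points, 0, noise_sigma))
  }
  data.frame(standard_amount = amounts, signal = signals)
}

#' End-to-end candidate recovery on synthetic data
#'
#' For each seed: simulate a proteome and its identification tables, run the
#' emPAI and candidate-selection pipeline, and score the retained list
#' against ground truth. Sensitivity is the fraction of COS-specific proteins
#' above the abundance floor (COS emPAI at least 1/100 of the reference
#' maximum) that are retained; the false-discovery proportion is the fraction
#' of retained proteins that are not COS-specific.
#'
#' @param seeds integer vector of simulation seeds.
#' @param n_proteins proteome size per simulation.
#' @param class_proportions passed to [simulate_proteome()].
#' @param detection a [detection_model()].
#' @param config a [filter_config()].
#' @param rule a [digestion_rule()].
#' @return a data.frame with one row per seed: `seed`, `sensitivity`, `fdp`,
#'   `n_retained`, `spearman` (rank correlation of true COS amount and COS
#'   emPAI over proteins detected in the COS-rich fraction).
#' @export
evaluate_candidate_recovery <- function(seeds = 1:20, n_proteins = 300,
                                        class_proportions = NULL,
                                        detection = detection_model(),
                                        config = filter_config(),
                                        rule = digestion_rule()) {
  res <- lapply(seeds, function(s) {
    prot <- if (is.null(class_proportions)) {
      simulate_proteome(n_proteins, seed = s)
    } else {
      simulate_proteome(n_proteins, class_proportions, seed = s)
    }
    ids <- simulate_fraction_tables(prot, rule = rule, detection = detection,
                                    seed = s + 10000L)
    fasta_df <- data.frame(protein_id = prot$protein_id,
                           description = prot$description,
                           sequence = prot$sequence, stringsAsFactors = FALSE)
    tab <- build_fraction_table(ids, fasta_df, rule = rule)
    cand <- build_candidate_list(tab, config = config)
    truth <- setNames(prot$localization_class, prot$protein_id)
    retained_ids <- cand$protein_id
    max_cos <- attr(cand, "max_empai_cos")
    floor_val <- max_cos * config$abundance_floor_frac
    cos_true <- prot$protein_id[prot$localization_class == "COS_specific"]
    cos_empai <- setNames(tab$COS, tab$protein_id)
    eligible <- cos_true[cos_empai[cos_true] >= floor_val]
    sens <- if (length(eligible)) {
      mean(eligible %in% retained_ids)
    } else NA_real_
    fdp <- if (length(retained_ids)) {
      mean(truth[retained_ids] != "COS_specific")
    } else NA_real_
    amounts <- attr(ids, "true_amounts")
    det <- tab$COS > 0
    rho <- if (sum(det) > 2) {
      cor(amounts[tab$protein_id[det], "COS"], tab$COS[det],
          method = "spearman")
    } else NA_real_
    data.frame(seed = s, sensitivity = sens, fdp = fdp,
               n_retained = length(retained_ids), spearman = rho)
  })
  do.call(rbind, res)
}
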