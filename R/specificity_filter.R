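# The core inference: the COS/(COS+CIS) share statistic, the three exclusion
# rules (share pre-filter, ROS presence, abundance floor), and the ranked
# candidate list with annotation classes.

ANNOTATION_CLASSES <- c("known_cos_specific", "known_elsewhere", "unassigned")
EXCLUSION_REASONS <- c("none", "low_share", "ros_presence", "low_abundance")

#' Filter configuration
#'
#' Thresholds of the candidate-selection rules, with the published defaults:
#' proteins with COS/(COS+CIS) below 0.5 are dropped outright; proteins whose
#' equal-volume ROS emPAI is more than 1/10 of their COS emPAI are excluded;
#' proteins below 1/100 of the most abundant surviving candidate are excluded;
#' the reported list keeps shares of at least 0.8.
#'
#' @param share_drop_below pre-filter share threshold (drop strictly below).
#' @param share_report_min reported-list share threshold (keep at or above;
#'   inclusive, applied to shares rounded to `share_digits` decimals).
#' @param ros_ratio_max maximum tolerated ROS/COS emPAI ratio ("more than"
#'   this is excluded, so the boundary itself is kept).
#' @param abundance_floor_frac abundance floor as a fraction of the maximum
#'   COS emPAI ("lower than" this is excluded).
#' @param ros_cos_volume_ratio multiplier applied to ROS emPAI before the
#'   1/10 comparison so rod and cone outer segments are compared at equal
#'   volume. The true rod:cone OS volume ratio is preparation-specific and not
#'   fixed by this package; default 1 (no correction) — set it explicitly when
#'   the geometry is known.
#' @param floor_reference `"survivors"` (default) computes the floor's
#'   reference maximum over proteins surviving the share and ROS filters;
#'   `"all"` uses every protein with a defined share.
#' @param share_digits decimal places at which the inclusive report boundary
#'   is applied.
#' @return a `filter_config` object.
#' @export
filter_config <- function(share_drop_below = 0.5, share_report_min = 0.8,
                          ros_ratio_max = 0.1, abundance_floor_frac = 0.01,
                          ros_cos_volume_ratio = 1.0,
                          floor_reference = c("survivors", "all"),
                          share_digits = 3) {
  if (!(share_drop_below > 0 && share_drop_below <= share_report_min &&
        share_report_min < 1)) {
    stop("need 0 < share_drop_below <= share_report_min < 1")
  }
  if (!(ros_ratio_max > 0 && ros_ratio_max < 1)) {
    stop("ros_ratio_max must be in (0, 1)")
  }
  if (!(abundance_floor_frac > 0 && abundance_floor_frac < 1)) {
    stop("abundance_floor_frac must be in (0, 1)")
  }
  if (ros_cos_volume_ratio <= 0) stop("ros_cos_volume_ratio must be positive")
  structure(list(share_drop_below = share_drop_below,
                 share_report_min = share_report_min,
                 ros_ratio_max = ros_ratio_max,
                 abundance_floor_frac = abundance_floor_frac,
                 ros_cos_volume_ratio = ros_cos_volume_ratio,
                 floor_reference = match.arg(floor_reference),
                 share_digits = share_digits),
            class = "filter_config")
}

#' COS share of a protein's outer/inner-segment abundance
#'
#' `empai_cos / (empai_cos + empai_cis)`: the portion of the protein detected
#' in the COS-rich fraction out of its total across the COS-rich and CIS-rich
#' fractions. 1 means detected only in the COS-rich fraction; 0.5 means equal
#' amounts in both.
#'
#' @param empai_cos,empai_cis cell-normalized emPAI values, both >= 0, not
#'   both 0 (a protein absent from both fractions has no defined share).
#' @return share in `[0, 1]` (vectorized).
#' @export
cos_share <- function(empai_cos, empai_cis) {
  if (any(empai_cos < 0) || any(empai_cis < 0)) {
    stop("emPAI values must be non-negative")
  }
  total <- empai_cos + empai_cis
  if (any(total == 0)) {
    stop("share undefined: protein absent from both COS and CIS fractions")
  }
  empai_cos / total
}

#' ROS-presence exclusion rule
#'
#' A protein also present in the ROS-rich fraction is excluded when its
#' equal-volume ROS emPAI is more than `ros_ratio_max` (default 1/10) of its
#' COS emPAI. Strict inequality: exactly 1/10 is kept.
#'
#' @param empai_ros_equal_volume ROS emPAI already multiplied by the volume
#'   correction (see [filter_config()]).
#' @param empai_cos COS emPAI.
#' @param config a [filter_config()].
#' @return logical: `TRUE` = keep, `FALSE` = drop (vectorized).
#' @export
ros_exclusion <- function(empai_ros_equal_volume, empai_cos,
                          config = filter_config()) {
  !(empai_ros_equal_volume > empai_cos * config$ros_ratio_max)
}

#' Abundance-floor exclusion rule
#'
#' Proteins whose COS emPAI is lower than `abundance_floor_frac` (default
#' 1/100) of the most abundantly detected candidate are excluded. Strict
#' inequality: exactly the floor is kept.
#'
#' @param empai_cos COS emPAI value(s).
#' @param max_empai_cos reference maximum over the candidate pool.
#' @param config a [filter_config()].
#' @return logical: `TRUE` = keep, `FALSE` = drop (vectorized).
#' @export
abundance_floor <- function(empai_cos, max_empai_cos,
                            config = filter_config()) {
  if (max_empai_cos <= 0) stop("max_empai_cos must be positive")
  !(empai_cos < max_empai_cos * config$abundance_floor_frac)
}

#' Build the ranked candidate list
#'
#' Applies the full selection pipeline to a protein-by-fraction emPAI table:
#' \enumerate{
#'   \item compute shares for proteins with `empai_cos + empai_cis > 0`
#'     (proteins absent from both are set aside with a logged count);
#'   \item drop shares below `share_drop_below`;
#'   \item apply the ROS-presence rule with volume-corrected ROS values;
#'   \item apply the abundance floor, with the reference maximum taken over
#'     the survivors of the previous steps;
#'   \item report records whose share (rounded to `share_digits`) is at least
#'     `share_report_min`, sorted by share descending, ties broken by
#'     `empai_cos` descending, then `protein_id` ascending.
#' }
#'
#' @param table a fraction emPAI table from [build_fraction_table()] (columns
#'   `protein_id`, `ROS`, `RIS`, `COS`, `CIS`; `ROS`/`RIS` optional and
#'   treated as 0 when absent).
#' @param annotations optional named character vector or data.frame
#'   (`protein_id`, `annotation_class`) assigning known localization classes;
#'   proteins without an entry are `"unassigned"`.
#' @param config a [filter_config()].
#' @param share optional numeric vector (parallel to `table` rows) of
#'   externally supplied shares — used when re-evaluating a published list
#'   whose shares were computed from unrounded values no longer available;
#'   when given, filtering and ordering use these instead of recomputing from
#'   the (possibly rounded) emPAI columns.
#' @return a data.frame of retained candidates (class `candidate_list`) with
#'   columns `protein_id`, `description`, `empai_cos`, `empai_cis`, `share`,
#'   `retained`, `exclusion_reason`, `annotation_class`; attributes
#'   `all_records` (every scored protein with its exclusion reason),
#'   `excluded_tallies`, `n_unscored`, `max_empai_cos` and `config`.
#' @export
build_candidate_list <- function(table, annotations = NULL,
                                 config = filter_config(), share = NULL) {
  stopifnot(is.data.frame(table), "protein_id" %in% names(table),
            "COS" %in% names(table), "CIS" %in% names(table))
  ros <- if ("ROS" %in% names(table)) table$ROS else rep(0, nrow(table))
  desc <- if ("description" %in% names(table)) table$description else ""

  rec <- data.frame(protein_id = table$protein_id,
                    description = desc,
                    empai_cos = table$COS,
                    empai_cis = table$CIS,
                    empai_ros = ros,
                    stringsAsFactors = FALSE)
  if (!is.null(share)) {
    if (length(share) != nrow(rec)) stop("share override length mismatch")
    rec$share <- share
  }

  scored <- rec$empai_cos + rec$empai_cis > 0
  n_unscored <- sum(!scored)
  if (n_unscored > 0) {
    cf_log("INFO", n_unscored, " protein(s) absent from both COS and CIS ",
           "fractions: not scored")
  }
  rec <- rec[scored, , drop = FALSE]
  if (is.null(share)) {
    rec$share <- cos_share(rec$empai_cos, rec$empai_cis)
  }

  reason <- rep("none", nrow(rec))
  # (2) share pre-filter
  reason[rec$share < config$share_drop_below] <- "low_share"
  # (3) ROS-presence rule on equal-volume ROS values
  ros_ev <- rec$empai_ros * config$ros_cos_volume_ratio
  drop_ros <- reason == "none" & !ros_exclusion(ros_ev, rec$empai_cos, config)
  reason[drop_ros] <- "ros_presence"
  # (4) abundance floor over survivors (or the whole scored pool)
  pool <- if (config$floor_reference == "survivors") reason == "none"
          else rep(TRUE, nrow(rec))
  max_cos <- if (any(pool)) max(rec$empai_cos[pool]) else NA_real_
  if (!is.na(max_cos) && max_cos > 0) {
    drop_floor <- reason == "none" &
      !abundance_floor(rec$empai_cos, max_cos, config)
    reason[drop_floor] <- "low_abundance"
  }
  # (5) report threshold, inclusive on rounded shares
  share_r <- round(rec$share, config$share_digits)
  below_report <- reason == "none" & share_r < config$share_report_min
  reason[below_report] <- "low_share"

  rec$retained <- reason == "none"
  rec$exclusion_reason <- reason
  rec$annotation_class <- .lookup_annotation(rec$protein_id, annotations)

  ord <- order(-rec$share, -rec$empai_cos, rec$protein_id)
  rec <- rec[ord, , drop = FALSE]
  out <- rec[rec$retained, setdiff(names(rec), "empai_ros"), drop = FALSE]
  rownames(out) <- NULL
  rownames(rec) <- NULL
  attr(out, "all_records") <- rec
  attr(out, "excluded_tallies") <- base::table(factor(reason[reason != "none"],
                                                      levels = EXCLUSION_REASONS[-1]))
  attr(out, "n_unscored") <- n_unscored
  attr(out, "max_empai_cos") <- max_cos
  attr(out, "config") <- config
  class(out) <- c("candidate_list", class(out))
  out
}

.lookup_annotation <- function(protein_id, annotations) {
  if (is.null(annotations)) return(rep("unassigned", length(protein_id)))
  if (is.data.frame(annotations)) {
    annotations <- setNames(annotations$annotation_class,
                            annotations$protein_id)
  }
  bad <- !annotations %in% ANNOTATION_CLASSES
  if (any(bad)) {
    stop("unknown annotation class(es): ",
         paste(unique(annotations[bad]), collapse = ", "))
  }
  cls <- unname(annotations[protein_id])
  cls[is.na(cls)] <- "unassigned"
  cls
}

#' Count candidates per annotation class
#'
#' @param records a candidate data.frame carrying `annotation_class`.
#' @return named integer vector over the three classes (known COS-specific,
#'   known elsewhere, unassigned); counts sum to `nrow(records)`.
#' @export
classify_candidates <- function(records) {
  stopifnot("annotation_class" %in% names(records))
  counts <- base::table(factor(records$annotation_class,
                               levels = ANNOTATION_CLASSES))
  setNames(as.integer(counts), ANNOTATION_CLASSES)
}
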