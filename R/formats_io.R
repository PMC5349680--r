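# Readers and writers for the external formats the pipeline touches:
# protein FASTA, peptide identification tables, marker-recovery tables,
# absorbance spectra, candidate tables and YAML/JSON configuration.

STANDARD_AA <- strsplit("ACDEFGHIKLMNPQRSTVWY", "")[[1]]

#' Read a protein FASTA file
#'
#' Sequences are uppercased and validated against the 20 standard one-letter
#' amino-acid codes. Record order is preserved.
#'
#' @param path path to a FASTA file of amino-acid sequences.
#' @param allow_x if `TRUE`, tolerate `X` (unknown residue) in sequences;
#'   peptides containing `X` are later dropped from observable sets.
#' @return a data.frame with columns `protein_id`, `description`, `sequence`.
#' @examples
#' fa <- tempfile(fileext = ".fasta")
#' writeLines(c(">p1 demo", "MKAVLR", ">p2", "ggwirk"), fa)
#' read_fasta(fa)
#' @export
read_fasta <- function(path, allow_x = FALSE) {
  if (!file.exists(path)) stop("FASTA file not found: ", path)
  aa <- Biostrings::readAAStringSet(path)
  if (length(aa) == 0L) stop("FASTA file is empty: ", path)
  headers <- names(aa)
  ids <- sub("\\s.*$", "", headers)
  desc <- ifelse(grepl("\\s", headers), sub("^\\S+\\s+", "", headers), "")
  if (anyDuplicated(ids)) {
    stop("duplicate protein_id in FASTA: ",
         paste(unique(ids[duplicated(ids)]), collapse = ", "))
  }
  seqs <- toupper(as.character(aa))
  allowed <- c(STANDARD_AA, if (allow_x) "X")
  bad <- vapply(seqs, function(s) {
    any(!strsplit(s, "")[[1]] %in% allowed)
  }, logical(1))
  if (any(bad)) {
    stop("non-standard residues in sequence(s): ",
         paste(ids[bad], collapse = ", "))
  }
  data.frame(protein_id = ids, description = desc, sequence = unname(seqs),
             stringsAsFactors = FALSE)
}

#' Read a peptide identification table
#'
#' Expects delimited text with columns `fraction_id`, `protein_id`,
#' `peptide_sequence` and optionally `replicate_id` (defaulting to 1). Each row
#' is one accepted identification; duplicate (fraction, protein, peptide,
#' replicate) rows are collapsed, matching the distinct-peptide semantics under
#' which emPAI counts observed peptides.
#'
#' @param path path to the table.
#' @param sep field separator; tab by default, use "," for CSV exports.
#' @param fractions allowed fraction identifiers.
#' @param col_map optional named character vector mapping the required column
#'   names to the names used in the file, e.g.
#'   `c(protein_id = "prot_acc", peptide_sequence = "pep_seq")`. Lets Mascot
#'   CSV exports be ingested without editing.
#' @return a data.frame with columns `fraction_id`, `protein_id`,
#'   `peptide_sequence`, `replicate_id`, one row per distinct identification.
#' @export
read_id_table <- function(path, sep = "\t", fractions = FRACTIONS,
                          col_map = NULL) {
  if (!file.exists(path)) stop("identification table not found: ", path)
  df <- read.delim(path, sep = sep, stringsAsFactors = FALSE,
                   check.names = FALSE)
  if (!is.null(col_map)) {
    for (std in names(col_map)) {
      if (!col_map[[std]] %in% names(df)) {
        stop("mapped column not found in table: ", col_map[[std]])
      }
      names(df)[names(df) == col_map[[std]]] <- std
    }
  }
  required <- c("fraction_id", "protein_id", "peptide_sequence")
  missing_cols <- setdiff(required, names(df))
  if (length(missing_cols)) {
    stop("identification table missing column(s): ",
         paste(missing_cols, collapse = ", "))
  }
  if (!"replicate_id" %in% names(df)) df$replicate_id <- rep(1L, nrow(df))
  df <- df[, c(required, "replicate_id")]
  if (nrow(df) == 0L) return(df)
  bad_frac <- !df$fraction_id %in% fractions
  if (any(bad_frac)) {
    stop("unknown fraction_id at line(s) ",
         paste(which(bad_frac) + 1L, collapse = ", "), ": ",
         paste(unique(df$fraction_id[bad_frac]), collapse = ", "))
  }
  empty_pep <- !nzchar(df$peptide_sequence)
  if (any(empty_pep)) {
    stop("empty peptide_sequence at line(s) ",
         paste(which(empty_pep) + 1L, collapse = ", "))
  }
  df$peptide_sequence <- toupper(df$peptide_sequence)
  df <- unique(df)
  rownames(df) <- NULL
  df
}

#' Write / read the candidate table
#'
#' Emits the ranked COS-candidate list as delimited text with a fixed column
#' set; shares are written at 3 decimals and emPAI values at 4, and a re-read
#' reproduces those values exactly (lossless at the emitted precision).
#'
#' @param records a candidate data.frame as produced by
#'   [build_candidate_list()].
#' @param path output path.
#' @param sep field separator.
#' @return `path`, invisibly.
#' @export
write_candidate_table <- function(records, path, sep = "\t") {
  cols <- c("protein_id", "description", "empai_cos", "empai_cis",
            "share", "annotation_class")
  if (!all(cols %in% names(records))) {
    stop("candidate records missing column(s): ",
         paste(setdiff(cols, names(records)), collapse = ", "))
  }
  out <- records[, cols]
  out$empai_cos <- sprintf("%.4f", out$empai_cos)
  out$empai_cis <- sprintf("%.4f", out$empai_cis)
  out$share <- sprintf("%.3f", out$share)
  ok <- tryCatch({
    write.table(out, path, sep = sep, quote = FALSE, row.names = FALSE)
    TRUE
  }, error = function(e) FALSE, warning = function(w) FALSE)
  if (!ok) stop("could not write candidate table to: ", path)
  invisible(path)
}

#' @rdname write_candidate_table
#' @export
read_candidate_table <- function(path, sep = "\t") {
  if (!file.exists(path)) stop("candidate table not found: ", path)
  df <- read.delim(path, sep = sep, stringsAsFactors = FALSE)
  num <- c("empai_cos", "empai_cis", "share")
  for (cn in intersect(num, names(df))) df[[cn]] <- as.numeric(df[[cn]])
  df
}

#' Read a marker-recovery table
#'
#' Delimited text with columns `marker`, `compartment`, `fraction`, `percent`
#' and optionally `sem`, mirroring a membrane-recovery experiment: each row is
#' the percentage of a marker protein recovered in an upper or lower gradient
#' fraction relative to the initial membranes. Missing measurements
#' (signal not detected) may be encoded as `NA` or `ND`.
#'
#' @param path path to the table.
#' @param sep field separator.
#' @return a data.frame with `percent` and `sem` numeric (`NA` where not
#'   detected).
#' @export
read_marker_table <- function(path, sep = "\t") {
  if (!file.exists(path)) stop("marker table not found: ", path)
  df <- read.delim(path, sep = sep, stringsAsFactors = FALSE)
  required <- c("marker", "compartment", "fraction", "percent")
  missing_cols <- setdiff(required, names(df))
  if (length(missing_cols)) {
    stop("marker table missing column(s): ",
         paste(missing_cols, collapse = ", "))
  }
  df$percent[df$percent %in% c("ND", "N.D.", "nd")] <- NA
  df$percent <- as.numeric(df$percent)
  if (!"sem" %in% names(df)) df$sem <- NA_real_
  df$sem <- suppressWarnings(as.numeric(df$sem))
  neg <- !is.na(df$percent) & df$percent < 0
  if (any(neg)) {
    stop("negative recovery percent at line(s) ",
         paste(which(neg) + 1L, collapse = ", "))
  }
  df
}

#' Read an absorbance spectrum series
#'
#' Delimited text with a `wavelength` column (nm, strictly increasing) and one
#' column per bleach step, ordered left to right from the pre-bleach spectrum.
#'
#' @param path path to the table.
#' @param sep field separator.
#' @return a `spectrum_series` object: list with `wavelength` (numeric grid),
#'   `curves` (matrix, one column per step) and `step_labels`.
#' @export
read_spectra <- function(path, sep = "\t") {
  if (!file.exists(path)) stop("spectra table not found: ", path)
  df <- read.delim(path, sep = sep, stringsAsFactors = FALSE)
  if (!"wavelength" %in% names(df)) stop("spectra table needs a 'wavelength' column")
  curves <- as.matrix(df[, setdiff(names(df), "wavelength"), drop = FALSE])
  spectrum_series(df$wavelength, curves, colnames(curves))
}

#' Construct a spectrum series
#'
#' @param wavelength strictly increasing wavelength grid in nm.
#' @param curves numeric matrix of absorbances, one column per bleach step.
#' @param step_labels optional labels, one per curve.
#' @return a `spectrum_series` object.
#' @export
spectrum_series <- function(wavelength, curves,
                            step_labels = colnames(curves)) {
  curves <- as.matrix(curves)
  if (any(diff(wavelength) <= 0)) stop("wavelength grid must be strictly increasing")
  if (nrow(curves) != length(wavelength)) {
    stop("each curve must share the wavelength grid length")
  }
  if (is.null(step_labels)) step_labels <- paste0("curve", seq_len(ncol(curves)))
  structure(list(wavelength = wavelength, curves = curves,
                 step_labels = step_labels),
            class = "spectrum_series")
}

#' Write a spectrum series
#'
#' @param series a `spectrum_series`.
#' @param path output path.
#' @param sep field separator.
#' @export
write_spectra <- function(series, path, sep = "\t") {
  stopifnot(inherits(series, "spectrum_series"))
  df <- data.frame(wavelength = series$wavelength, series$curves,
                   check.names = FALSE)
  write.table(df, path, sep = sep, quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Load a pipeline configuration document
#'
#' A flat YAML or JSON namespace holding every tunable threshold with its
#' default. Unknown keys are rejected so typos cannot silently fall back to
#' defaults.
#'
#' @param path path to a `.yaml`/`.yml` or `.json` file; `NULL` returns the
#'   full default configuration.
#' @return a named list of configuration values.
#' @export
load_config <- function(path = NULL) {
  defaults <- list(
    share_drop_below = 0.5,
    share_report_min = 0.8,
    ros_ratio_max = 0.1,
    abundance_floor_frac = 0.01,
    ros_cos_volume_ratio = 1.0,
    floor_reference = "survivors",
    is_os_volume_ratio = 6,
    cells_reference = 5e4,
    observable_min_da = 800,
    observable_max_da = 4500,
    missed_cleavages = 0,
    seed = 1
  )
  if (is.null(path)) return(defaults)
  if (!file.exists(path)) stop("config file not found: ", path)
  user <- if (grepl("\\.json$", path, ignore.case = TRUE)) {
    jsonlite::read_json(path, simplifyVector = TRUE)
  } else {
    yaml::read_yaml(path)
  }
  unknown <- setdiff(names(user), names(defaults))
  if (length(unknown)) {
    stop("unknown configuration key(s): ", paste(unknown, collapse = ", "))
  }
  utils::modifyList(defaults, user)
}
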