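# Shared fixtures, built in code at test time.

write_toy_fasta <- function(lines, path = tempfile(fileext = ".fasta")) {
  writeLines(lines, path)
  path
}

# The published reference candidate list reshaped into a fraction emPAI table
# (no ROS/RIS entries survive in the published list).
reference_fraction_table <- function() {
  ref <- cos_reference_candidates()
  data.frame(protein_id = ref$protein_id, ROS = 0, RIS = 0,
             COS = ref$empai_cos, CIS = ref$empai_cis,
             stringsAsFactors = FALSE)
}

reference_annotations <- function() {
  ref <- cos_reference_candidates()
  data.frame(protein_id = ref$protein_id,
             annotation_class = ref$annotation_class,
             stringsAsFactors = FALSE)
}

# Brute-force digestion oracle: scan every inter-residue boundary and cleave
# where the K/R-not-before-P rule says so. Independent of the implementation.
digest_oracle <- function(sequence) {
  res <- strsplit(sequence, "")[[1]]
  n <- length(res)
  peps <- character(0)
  start <- 1L
  if (n > 1L) {
    for (i in seq_len(n - 1L)) {
      if (res[i] %in% c("K", "R") && res[i + 1L] != "P") {
        peps <- c(peps, paste(res[start:i], collapse = ""))
        start <- i + 1L
      }
    }
  }
  c(peps, paste(res[start:n], collapse = ""))
}

random_aa_sequence <- function(len) {
  paste(sample(strsplit("ACDEFGHIKLMNPQRSTVWY", "")[[1]], len, replace = TRUE),
        collapse = "")
}

cone_pigment_templates <- function() {
  list(pigment_template("red", 622),
       pigment_template("green", 535),
       pigment_template("blue", 460))
}
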