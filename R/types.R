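# Domain objects: genome references, crRNA-matched target sites, and
# transposon donor configurations. All coordinates in the package are
# 0-based, half-open.

#' Construct a genome reference
#'
#' @param name Text label for the sequence.
#' @param sequence DNA string over A/C/G/T (upper case enforced).
#' @return An object of class `genome_ref` with fields `name` and `sequence`.
#' @export
genome_ref <- function(name, sequence) {
  sequence <- toupper(sequence)
  if (!is.character(sequence) || length(sequence) != 1L || nchar(sequence) < 1L)
    .stop_invalid("reference sequence must be a single non-empty string")
  if (grepl("[^ACGT]", sequence))
    .stop_invalid("reference alphabet is strictly A/C/G/T")
  structure(list(name = as.character(name), sequence = sequence),
            class = "genome_ref")
}

#' @export
print.genome_ref <- function(x, ...) {
  cat(sprintf("<genome_ref> %s: %d bp, GC %.3f\n", x$name,
              nchar(x$sequence), gc_fraction(x$sequence)))
  invisible(x)
}

#' GC fraction of a DNA string
#' @param sequence DNA string.
#' @return Fraction of G+C bases.
#' @export
gc_fraction <- function(sequence) {
  n <- nchar(sequence)
  if (n == 0L) return(NA_real_)
  gc <- nchar(gsub("[AT]", "", sequence))
  gc / n
}

#' Define the crRNA-complementary target site
#'
#' The target site is the genomic interval complementary to the crRNA spacer;
#' RNA-guided integration occurs a fixed distance downstream of its 3' end.
#' `three_prime_end` is the 0-based coordinate just past the target in
#' target-strand orientation: `end` for a plus-strand site, `start` for a
#' minus-strand site.
#'
#' @param ref A `genome_ref`.
#' @param start,end 0-based half-open interval of the target sequence.
#' @param strand "+" or "-".
#' @param pam Short PAM sequence (annotation only).
#' @return An object of class `target_site`.
#' @export
target_site <- function(ref, start, end, strand = "+", pam = "") {
  L <- nchar(ref$sequence)
  if (!(start >= 0 && start < end && end <= L))
    .stop_invalid("target interval must satisfy 0 <= start < end <= reference length")
  if (!strand %in% c("+", "-")) .stop_invalid("strand must be '+' or '-'")
  structure(list(ref_name = ref$name, start = as.integer(start),
                 end = as.integer(end), strand = strand, pam = pam,
                 three_prime_end = if (strand == "+") as.integer(end) else as.integer(start)),
            class = "target_site")
}

#' @export
print.target_site <- function(x, ...) {
  cat(sprintf("<target_site> %s:[%d,%d) strand %s, 3' end at %d\n",
              x$ref_name, x$start, x$end, x$strand, x$three_prime_end))
  invisible(x)
}

#' Construct a transposon donor configuration
#'
#' The mobilized element is `right_end + cargo + left_end`; the right-end 5'
#' terminus and the left-end 3' terminus are the sequences joined to genomic
#' DNA on integration. For plasmid donors `backbone` is the non-mobilized
#' vector sequence whose presence in an integration product marks a
#' cointegrate.
#'
#' @param right_end,left_end Transposon end sequences (each >= 20 bp, distinct).
#' @param cargo DNA payload between the ends.
#' @param backbone Plasmid backbone DNA ("" for linear donors).
#' @return An object of class `donor_config`.
#' @export
donor_config <- function(right_end, left_end, cargo, backbone = "") {
  for (s in c(right_end, left_end, cargo, backbone))
    if (grepl("[^ACGT]", toupper(s))) .stop_invalid("donor sequences must be A/C/G/T")
  right_end <- toupper(right_end); left_end <- toupper(left_end)
  cargo <- toupper(cargo); backbone <- toupper(backbone)
  if (nchar(right_end) < 20L || nchar(left_end) < 20L)
    .stop_invalid("transposon ends must each be >= 20 bp")
  if (identical(right_end, left_end))
    .stop_invalid("right and left ends must differ")
  structure(list(right_end = right_end, left_end = left_end, cargo = cargo,
                 backbone = backbone, cargo_size_bp = nchar(cargo)),
            class = "donor_config")
}

#' @export
print.donor_config <- function(x, ...) {
  cat(sprintf("<donor_config> RE %d bp, LE %d bp, cargo %d bp, backbone %d bp\n",
              nchar(x$right_end), nchar(x$left_end), x$cargo_size_bp,
              nchar(x$backbone)))
  invisible(x)
}

#' Generate a synthetic donor configuration
#'
#' Random transposon ends, cargo and (optionally) plasmid backbone at the
#' given sizes; deterministic for a fixed seed.
#'
#' @param cargo_size_bp Cargo length (default 1000, a 1-kb payload).
#' @param end_len Length of each transposon end.
#' @param backbone_len Plasmid backbone length (0 for a linear donor).
#' @param gc GC fraction of the generated sequences.
#' @param seed Integer RNG seed.
#' @return A `donor_config`.
#' @export
make_donor <- function(cargo_size_bp = 1000, end_len = 100, backbone_len = 2000,
                       gc = 0.5, seed = 1) {
  with_seed(seed, {
    donor_config(right_end = random_dna(end_len, gc),
                 left_end = random_dna(end_len, gc),
                 cargo = random_dna(cargo_size_bp, gc),
                 backbone = if (backbone_len > 0) random_dna(backbone_len, gc) else "")
  })
}

# ---- canonical (target-strand) frame ----------------------------------------
# All junction geometry is defined in the orientation of the target strand.
# For a minus-strand site we reverse-complement the reference so the site
# becomes plus-strand, compute there, and map coordinates back. This makes
# strand-mirror invariance hold by construction.

canonical_frame <- function(ref, site) {
  L <- nchar(ref$sequence)
  if (site$strand == "+")
    return(list(ref = ref, site = site, flipped = FALSE, L = L))
  ref2 <- genome_ref(ref$name, revcomp(ref$sequence))
  site2 <- target_site(ref2, L - site$end, L - site$start, "+", site$pam)
  list(ref = ref2, site = site2, flipped = TRUE, L = L)
}

# Map the start of a half-open interval [pos0, pos0+len) between frames.
flip_interval_start <- function(pos0, len, L) L - pos0 - len
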