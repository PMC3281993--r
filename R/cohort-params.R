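#' Parameters of the synthetic cohort generator
#'
#' Bundles every knob of the synthetic data generator: a founder genome
#' carrying population germline variation, two independently sequenced
#' normal genomes, two tumour lineages diverging from a progenitor with
#' Poisson-distributed somatic mutation counts drawn from a
#' transversion-skewed spectrum, flow-sorted chromosome sequencing libraries
#' with bounded cross-contamination, chimeric contigs for misassembly
#' detection, and a genotyped multi-tumour cohort with planted
#' metastasis / reinfection / de novo host cases and a regional selective
#' sweep.
#'
#' Defaults are a desk-scale rendition of the study system: a 7-chromosome
#' nuclear genome, germline heterozygosity of about 2 x 10^-4 variants/bp, a
#' 16-nuclear + 21-mitochondrial somatic marker panel typed across 104
#' tumours from 69 hosts, and flow-sorted libraries that are ~90% pure
#' (10% cross-contamination).
#'
#' @param genome_length Total nuclear genome length, bp.
#' @param n_contigs Number of assembly contigs the genome is split into.
#' @param n_chromosomes Number of chromosomes (flow-sortable peaks).
#' @param germline_het_rate Population germline variant rate, variants/bp.
#' @param founder_private_rate Founder-private germline rate, variants/bp.
#' @param somatic_rate_per_branch Expected somatic substitutions acquired by
#'   each tumour lineage after divergence (Poisson mean).
#' @param somatic_rate_trunk Expected somatic substitutions on the shared
#'   trunk before divergence (Poisson mean); the trunk/branch split is not
#'   an observable of the four-genome design, so it is exposed rather than
#'   fixed.
#' @param spectrum_weights Probabilities of the six strand-collapsed
#'   substitution classes for *somatic* mutations, in the order
#'   A:T>C:G, A:T>G:C, A:T>T:A, G:C>A:T, G:C>C:G, G:C>T:A. The default
#'   elevates the three transversion classes characteristic of the tumour
#'   lineage.
#' @param germline_spectrum_weights Same, for germline variants; the default
#'   is transition-dominated.
#' @param cnv_loss_fraction Fraction of the genome lost hemizygously per
#'   tumour lineage (one contiguous segment); heterozygous variants in the
#'   segment are dropped or homozygosed with equal probability.
#' @param n_tumors,n_hosts Genotyped cohort size.
#' @param n_nuclear_markers,n_mito_markers Somatic marker panel sizes.
#' @param n_clone_genotypes Distinct tumour genotypes in the simulated clone
#'   tree (before de novo variants).
#' @param library_contamination Fraction of each flow-sorted library's reads
#'   reassigned to other chromosomes, in `[0, 0.5]`.
#' @param library_read_density Mapped chromosome-library reads per contig
#'   bp.
#' @param chimera_fraction Fraction of contigs made chimeric (two-chromosome
#'   joins).
#' @param mito_length,mito_control_region Mitochondrial genome length and
#'   control-region interval (0-based half-open), bp.
#' @param seed Integer seed; a fixed seed makes every generator output
#'   byte-identical.
#' @return A validated list of class `cohort_params`.
#' @export
cohort_params <- function(genome_length = 5e5,
                          n_contigs = 20,
                          n_chromosomes = 7,
                          germline_het_rate = 2e-4,
                          founder_private_rate = 5e-5,
                          somatic_rate_per_branch = 500,
                          somatic_rate_trunk = 500,
                          spectrum_weights = c(0.10, 0.15, 0.20,
                                               0.25, 0.10, 0.20),
                          germline_spectrum_weights = c(0.07, 0.28, 0.07,
                                                        0.38, 0.05, 0.15),
                          cnv_loss_fraction = 0.02,
                          n_tumors = 104,
                          n_hosts = 69,
                          n_nuclear_markers = 16,
                          n_mito_markers = 21,
                          n_clone_genotypes = 12,
                          library_contamination = 0.1,
                          library_read_density = 0.04,
                          chimera_fraction = 0.05,
                          mito_length = 17000,
                          mito_control_region = c(15500, 17000),
                          seed = 1L) {
  check_scalar_number(genome_length, "genome_length", min = 1)
  check_scalar_number(n_contigs, "n_contigs", min = 1)
  check_scalar_number(n_chromosomes, "n_chromosomes", min = 1)
  for (nm in c("germline_het_rate", "founder_private_rate",
               "somatic_rate_per_branch", "somatic_rate_trunk",
               "cnv_loss_fraction", "library_read_density")) {
    check_scalar_number(get(nm), nm, min = 0)
  }
  check_scalar_number(library_contamination, "library_contamination",
                      min = 0, max = 0.5)
  check_scalar_number(chimera_fraction, "chimera_fraction", min = 0, max = 1)
  for (w in list(spectrum_weights, germline_spectrum_weights)) {
    if (length(w) != 6 || any(w < 0) || abs(sum(w) - 1) > 1e-8) {
      abort("spectrum weights must be 6 non-negative values summing to 1")
    }
  }
  check_scalar_number(seed, "seed")
  out <- list(
    genome_length = as.integer(genome_length),
    n_contigs = as.integer(n_contigs),
    n_chromosomes = as.integer(n_chromosomes),
    germline_het_rate = germline_het_rate,
    founder_private_rate = founder_private_rate,
    somatic_rate_per_branch = somatic_rate_per_branch,
    somatic_rate_trunk = somatic_rate_trunk,
    spectrum_weights = setNames(spectrum_weights, SUBSTITUTION_CLASSES),
    germline_spectrum_weights = setNames(germline_spectrum_weights,
                                         SUBSTITUTION_CLASSES),
    cnv_loss_fraction = cnv_loss_fraction,
    n_tumors = as.integer(n_tumors),
    n_hosts = as.integer(n_hosts),
    n_nuclear_markers = as.integer(n_nuclear_markers),
    n_mito_markers = as.integer(n_mito_markers),
    n_clone_genotypes = as.integer(n_clone_genotypes),
    library_contamination = library_contamination,
    library_read_density = library_read_density,
    chimera_fraction = chimera_fraction,
    mito_length = as.integer(mito_length),
    mito_control_region = mito_control_region,
    seed = as.integer(seed)
  )
  class(out) <- "cohort_params"
  out
}

#' @export
print.cohort_params <- function(x, ...) {
  cat(sprintf(
    "<cohort_params> %s bp genome in %d contigs / %d chromosomes; %d tumours, %d hosts; seed %d\n",
    format(x$genome_length, big.mark = ","), x$n_contigs, x$n_chromosomes,
    x$n_tumors, x$n_hosts, x$seed))
  invisible(x)
}
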