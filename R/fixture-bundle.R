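#' Write and re-read a synthetic cohort as analysis-ready files
#'
#' Serialises the generator outputs in the formats the analysis functions
#' consume -- FASTA for the reference contigs, minimal VCF 4.2 for the four
#' variant sets, TSV for the chromosome-library profiles and the genotype
#' matrix, JSON for the truth record -- and returns a manifest of paths and
#' md5 checksums. With a fixed generator seed the checksums are
#' reproducible.
#'
#' @param outputs A named list with any of the components `reference`
#'   (from [simulate_reference()]), `cohort` ([simulate_cohort()]),
#'   `libraries` ([simulate_chromosome_libraries()]), `genotypes`
#'   ([simulate_genotype_cohort()]).
#' @param directory Output directory (created if needed).
#' @return A tibble manifest: `component`, `path`, `md5`. Also written to
#'   `manifest.json` in the directory.
#' @export
write_fixture_bundle <- function(outputs, directory) {
  if (!dir.exists(directory)) {
    ok <- dir.create(directory, recursive = TRUE, showWarnings = FALSE)
    if (!ok) abort(paste0("cannot create directory ", directory))
  }
  if (file.access(directory, mode = 2) != 0) {
    abort(paste0("directory not writable: ", directory))
  }
  files <- list()
  put <- function(component, filename) {
    files[[length(files) + 1L]] <<- tibble(component = component,
                                           path = file.path(directory,
                                                            filename))
    file.path(directory, filename)
  }
  truth <- list()
  if (!is.null(outputs$reference)) {
    ref <- outputs$reference
    seqs <- Biostrings::DNAStringSet(ref$sequences)
    Biostrings::writeXStringSet(seqs, put("reference", "reference.fasta"))
    readr::write_tsv(ref$contigs, put("reference", "contigs.tsv"))
    truth$contig_map <- ref$contigs
    truth$chromosomes <- ref$chromosomes
  }
  if (!is.null(outputs$cohort)) {
    co <- outputs$cohort
    lens <- setNames(co$reference$contigs$length, co$reference$contigs$contig)
    for (s in names(co$variants)) {
      write_minimal_vcf(co$variants[[s]], lens,
                        put("cohort", paste0(s, ".vcf")), sample = s)
    }
    truth$variant_origins <- co$truth$origins
    truth$founder_variants <- co$truth$founder_variants
    truth$branch_a <- co$truth$branch_a
    truth$branch_b <- co$truth$branch_b
    truth$trunk <- co$truth$trunk
    truth$cn_segments <- co$truth$cn_segments
  }
  if (!is.null(outputs$libraries)) {
    libs <- outputs$libraries
    readr::write_tsv(libs$profiles, put("libraries", "library_profiles.tsv"))
    readr::write_tsv(libs$libraries, put("libraries", "libraries.tsv"))
  }
  if (!is.null(outputs$genotypes)) {
    gc <- outputs$genotypes
    readr::write_tsv(gc$matrix, put("genotypes", "genotype_matrix.tsv"))
    truth$tumor_genotypes <- gc$truth$tumor_genotypes
    truth$host_classes <- gc$truth$host_classes
    truth$sweep <- gc$truth$sweep
    truth$clone_tree <- gc$truth$tree |>
      mutate(markers = vapply(.data$markers, paste, character(1),
                              collapse = ","))
  }
  truth_path <- put("truth", "truth.json")
  jsonlite::write_json(truth, truth_path, auto_unbox = TRUE, digits = NA,
                       pretty = TRUE, na = "null")
  manifest <- bind_rows(files) |>
    mutate(md5 = unname(tools::md5sum(.data$path)))
  jsonlite::write_json(manifest, file.path(directory, "manifest.json"),
                       auto_unbox = TRUE, pretty = TRUE)
  manifest
}

#' Write a minimal VCF 4.2 file
#'
#' Emits the subset of VCF used throughout: CHROM, POS, REF, ALT, QUAL,
#' INFO keys `MQ`, `BQ` and `CEND` (distance to the nearest contig end),
#' and a single-sample GT:DP column.
#'
#' @param variants Tibble with `contig`, `pos`, `ref`, `alt`, `genotype`
#'   and optionally `qual`, `depth`, `mq`, `bq`.
#' @param contig_lengths Named vector of contig lengths (for headers and
#'   `CEND`).
#' @param path Output file.
#' @param sample Sample name for the genotype column.
#' @return `path`, invisibly.
#' @export
write_minimal_vcf <- function(variants, contig_lengths, path,
                              sample = "sample") {
  variants <- as_tibble(variants)
  header <- c(
    "##fileformat=VCFv4.2",
    sprintf("##contig=<ID=%s,length=%d>", names(contig_lengths),
            as.integer(contig_lengths)),
    "##INFO=<ID=MQ,Number=1,Type=Integer,Description=\"Mapping quality\">",
    "##INFO=<ID=BQ,Number=1,Type=Integer,Description=\"Base quality\">",
    "##INFO=<ID=CEND,Number=1,Type=Integer,Description=\"Distance to contig end\">",
    "##FORMAT=<ID=GT,Number=1,Type=String,Description=\"Genotype\">",
    "##FORMAT=<ID=DP,Number=1,Type=Integer,Description=\"Read depth\">",
    paste0("#CHROM\tPOS\tID\tREF\tALT\tQUAL\tFILTER\tINFO\tFORMAT\t", sample)
  )
  if (nrow(variants) > 0) {
    cend <- pmin(variants$pos,
                 unname(contig_lengths[variants$contig]) - variants$pos + 1)
    col_or <- function(nm, default) {
      if (nm %in% names(variants)) variants[[nm]] else
        rep(default, nrow(variants))
    }
    qual <- col_or("qual", 60L)
    depth <- col_or("depth", 40L)
    mq <- col_or("mq", 60L)
    bq <- col_or("bq", 35L)
    gt <- ifelse(variants$genotype == "hom", "1/1", "0/1")
    body <- sprintf("%s\t%d\t.\t%s\t%s\t%d\t.\tMQ=%d;BQ=%d;CEND=%d\tGT:DP\t%s:%d",
                    variants$contig, variants$pos, variants$ref,
                    variants$alt, as.integer(qual), as.integer(mq),
                    as.integer(bq), as.integer(cend), gt, as.integer(depth))
    ord <- order(variants$contig, variants$pos)
    body <- body[ord]
  } else body <- character(0)
  writeLines(c(header, body), path)
  invisible(path)
}

#' Read a minimal VCF back into a variant tibble
#'
#' Uses `vcfR` when installed; otherwise falls back to a plain-text reader
#' sufficient for the minimal subset written by [write_minimal_vcf()].
#'
#' @param path VCF file path.
#' @return Tibble with `contig`, `pos`, `ref`, `alt`, `genotype`, `depth`.
#' @export
read_minimal_vcf <- function(path) {
  if (requireNamespace("vcfR", quietly = TRUE)) {
    v <- vcfR::read.vcfR(path, verbose = FALSE)
    fix <- as.data.frame(v@fix, stringsAsFactors = FALSE)
    if (nrow(fix) == 0) {
      return(tibble(contig = character(), pos = integer(), ref = character(),
                    alt = character(), genotype = character(),
                    depth = integer()))
    }
    gtmat <- vcfR::extract.gt(v, element = "GT")
    dpmat <- vcfR::extract.gt(v, element = "DP")
    return(tibble(
      contig = fix$CHROM, pos = as.integer(fix$POS),
      ref = fix$REF, alt = fix$ALT,
      genotype = ifelse(gtmat[, 1] %in% c("1/1", "1|1"), "hom", "het"),
      depth = as.integer(dpmat[, 1])
    ))
  }
  lines <- readr::read_lines(path)
  body <- lines[!startsWith(lines, "#")]
  if (length(body) == 0) {
    return(tibble(contig = character(), pos = integer(), ref = character(),
                  alt = character(), genotype = character(),
                  depth = integer()))
  }
  f <- stringr::str_split_fixed(body, "\t", 10)
  smp <- stringr::str_split_fixed(f[, 10], ":", 2)
  tibble(
    contig = f[, 1], pos = as.integer(f[, 2]), ref = f[, 4], alt = f[, 5],
    genotype = ifelse(smp[, 1] %in% c("1/1", "1|1"), "hom", "het"),
    depth = as.integer(smp[, 2])
  )
}
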