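#' Binary somatic genotype matrices
#'
#' A genotype matrix records, for each tumour, the presence (1), absence (0)
#' or missingness (`NA`) of each somatic marker in a small nuclear +
#' mitochondrial panel, alongside sample metadata. Metadata columns are
#' recognised by name (`tumor_id`, `devil_id`, `location`, `year`, `tissue`,
#' `latitude`, `longitude`); every other column is a marker.
#'
#' @name genotype_matrix
NULL

GENOTYPE_METADATA_COLS <- c("tumor_id", "devil_id", "location", "year",
                            "tissue", "latitude", "longitude")

#' Marker columns of a genotype matrix
#'
#' @param matrix A genotype-matrix data frame.
#' @return Character vector of marker column names.
#' @export
marker_columns <- function(matrix) {
  setdiff(names(matrix), GENOTYPE_METADATA_COLS)
}

validate_genotype_matrix <- function(matrix) {
  matrix <- as_tibble(matrix)
  if (!"tumor_id" %in% names(matrix)) {
    abort("genotype matrix needs a `tumor_id` column")
  }
  mk <- marker_columns(matrix)
  if (length(mk) == 0) abort("genotype matrix has no marker columns")
  vals <- unlist(matrix[mk], use.names = FALSE)
  if (!all(vals %in% c(0L, 1L, NA))) {
    abort("marker calls must be 0, 1 or NA")
  }
  all_missing <- apply(is.na(matrix[mk]), 1, all)
  if (any(all_missing)) {
    abort("every tumour needs at least one non-missing marker call")
  }
  matrix
}

#' Collapse tumours into distinct genotypes
#'
#' Tumours with identical marker vectors are merged into one genotype.
#' A tumour with missing calls is merged into a fully observed genotype only
#' when exactly one such genotype is compatible with its non-missing calls
#' (the unique-completion rule); otherwise it stays as its own unresolved
#' genotype. With marker panels this small, model-based imputation is not
#' justifiable, so no other completion is attempted.
#'
#' @param matrix A genotype matrix (see [genotype_matrix]).
#' @return A tibble of class `genotype_table`: `genotype_id`, `resolved`,
#'   `n_tumors`, list-columns `tumor_ids`, `markers` (markers called 1) and
#'   `pattern` (the named 0/1/NA vector). The tumour-to-genotype mapping is
#'   attached as attribute `assignment` (tibble `tumor_id`, `genotype_id`).
#' @export
collapse_genotypes <- function(matrix) {
  matrix <- validate_genotype_matrix(matrix)
  mk <- marker_columns(matrix)
  gmat <- as.matrix(matrix[mk])
  mode(gmat) <- "integer"
  key <- apply(gmat, 1, function(r) paste(ifelse(is.na(r), "?", r),
                                          collapse = ""))
  groups <- split(seq_len(nrow(matrix)), key)
  complete_keys <- names(groups)[!grepl("\\?", names(groups))]

  # unique-completion: fold a missing-data group into the single compatible
  # fully observed genotype, when there is exactly one
  assign_to <- setNames(names(groups), names(groups))
  for (kk in setdiff(names(groups), complete_keys)) {
    pat <- strsplit(kk, "")[[1]]
    obs <- pat != "?"
    compatible <- complete_keys[vapply(complete_keys, function(ck) {
      all(strsplit(ck, "")[[1]][obs] == pat[obs])
    }, logical(1))]
    if (length(compatible) == 1L) assign_to[kk] <- compatible
  }
  final_groups <- split(unlist(groups[names(assign_to)], use.names = FALSE),
                        rep(unname(assign_to), lengths(groups[names(assign_to)])))
  ord <- order(nchar(names(final_groups)) == 0,
               grepl("\\?", names(final_groups)),
               -lengths(final_groups), names(final_groups))
  final_groups <- final_groups[ord]
  out <- tibble(
    genotype_id = paste0("G", seq_along(final_groups)),
    resolved = !grepl("\\?", names(final_groups)),
    n_tumors = unname(lengths(final_groups)),
    tumor_ids = unname(lapply(final_groups,
                              function(i) matrix$tumor_id[i])),
    markers = lapply(names(final_groups), function(kk) {
      mk[strsplit(kk, "")[[1]] == "1"]
    }),
    pattern = lapply(names(final_groups), function(kk) {
      p <- strsplit(kk, "")[[1]]
      setNames(suppressWarnings(as.integer(p)), mk)
    })
  )
  assignment <- tibble(
    tumor_id = unlist(out$tumor_ids, use.names = FALSE),
    genotype_id = rep(out$genotype_id, out$n_tumors)
  )
  structure(out, assignment = assignment,
            markers_all = mk,
            class = c("genotype_table", class(out)))
}

#' @rdname collapse_genotypes
#' @param x A `genotype_table`.
#' @export
genotype_assignment <- function(x) {
  stopifnot(inherits(x, "genotype_table"))
  attr(x, "assignment")
}
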