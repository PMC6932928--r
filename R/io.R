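#' Beta-value from methylated/unmethylated intensities
#'
#' beta = M / (M + U), the fraction of the total probe intensity that is
#' methylated. No stabilising offset is added. A zero total intensity
#' yields \code{NA} (missing), not an error.
#'
#' @param meth_intensity,unmeth_intensity non-negative intensities
#'   (vectorised).
#' @return beta-values in \eqn{[0,1]}, \code{NA} where M + U = 0.
#' @export
compute_beta <- function(meth_intensity, unmeth_intensity) {
  if (any(meth_intensity < 0, na.rm = TRUE) ||
      any(unmeth_intensity < 0, na.rm = TRUE))
    stopf("intensities must be non-negative")
  total <- meth_intensity + unmeth_intensity
  out <- ifelse(total == 0, NA_real_, meth_intensity / total)
  out
}

#' Remove sex-chromosome, SNP-associated and cross-reactive probes
#'
#' Drops CpGs annotated to chromosomes X or Y, CpGs in a user-supplied
#' common-SNP list, and CpGs in a user-supplied cross-reactive list.
#' Survivor order is preserved, so the operation is idempotent.
#'
#' @param betas CpG-by-sample beta matrix with rownames.
#' @param probes probe annotation with columns \code{cpg_id} and
#'   \code{chromosome}; must cover every matrix CpG.
#' @param snp_list,crossreactive_list character vectors of CpG ids (may be
#'   empty).
#' @return the filtered beta matrix.
#' @export
filter_probes <- function(betas, probes, snp_list = character(0),
                          crossreactive_list = character(0)) {
  ids <- rownames(betas)
  missing_ann <- setdiff(ids, probes$cpg_id)
  if (length(missing_ann))
    stopf("CpG(s) missing from annotation: %s",
          paste(utils::head(missing_ann, 5), collapse = ", "))
  chrom <- probes$chromosome[match(ids, probes$cpg_id)]
  sex <- chrom %in% c("chrX", "chrY", "X", "Y")
  drop <- sex | ids %in% snp_list | ids %in% crossreactive_list
  betas[!drop, , drop = FALSE]
}

#' Read a dataset from TSV files
#'
#' Reads a beta matrix (first column = CpG id, remaining columns =
#' samples), a sample sheet, and a probe annotation table, reconciles
#' sample ids, and validates beta values. Reading is gzip-transparent.
#'
#' @param matrix_path,sample_sheet_path,annotation_path file paths.
#' @return list with \code{betas}, \code{samples}, \code{probes}.
#' @export
load_dataset <- function(matrix_path, sample_sheet_path, annotation_path) {
  mat_dt <- data.table::fread(matrix_path, sep = "\t", header = TRUE,
                              data.table = FALSE)
  cpg_ids <- as.character(mat_dt[[1L]])
  betas <- as.matrix(mat_dt[, -1L, drop = FALSE])
  rownames(betas) <- cpg_ids
  samples <- data.table::fread(sample_sheet_path, sep = "\t", header = TRUE,
                               data.table = FALSE)
  probes <- data.table::fread(annotation_path, sep = "\t", header = TRUE,
                              data.table = FALSE)
  if (anyDuplicated(cpg_ids))
    stopf("duplicate CpG id(s): %s",
          paste(unique(cpg_ids[duplicated(cpg_ids)]), collapse = ", "))
  if (anyDuplicated(samples$sample_id))
    stopf("duplicate sample id(s): %s",
          paste(unique(samples$sample_id[duplicated(samples$sample_id)]),
                collapse = ", "))
  extra_sheet <- setdiff(samples$sample_id, colnames(betas))
  extra_mat <- setdiff(colnames(betas), samples$sample_id)
  if (length(extra_sheet) || length(extra_mat))
    stopf("sample id mismatch; in sheet only: %s; in matrix only: %s",
          paste(extra_sheet, collapse = ", ") %z% "none",
          paste(extra_mat, collapse = ", ") %z% "none")
  bad <- which(!is.na(betas) & (betas < 0 | betas > 1), arr.ind = TRUE)
  if (nrow(bad))
    stopf("beta outside [0,1] at e.g. CpG %s, sample %s (value %g)",
          rownames(betas)[bad[1, 1]], colnames(betas)[bad[1, 2]],
          betas[bad[1, , drop = FALSE]])
  samples <- samples[match(colnames(betas), samples$sample_id), , drop = FALSE]
  rownames(samples) <- NULL
  if ("tissue_class" %in% names(samples))
    samples$tissue_class <- factor(samples$tissue_class,
                                   levels = tissue_classes())
  list(betas = betas, samples = samples, probes = probes)
}

`%z%` <- function(a, b) if (nzchar(a)) a else b

#' Write a dataset as TSV (+ truth as JSON)
#'
#' @param dataset list with \code{betas}, \code{samples}, \code{probes}
#'   and optionally \code{truth} (e.g. a \code{meth_sim}).
#' @param dir output directory, created if needed.
#' @return invisibly, the paths written.
#' @export
write_dataset <- function(dataset, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  mpath <- file.path(dir, "betas.tsv")
  spath <- file.path(dir, "samples.tsv")
  apath <- file.path(dir, "probes.tsv")
  mat <- data.frame(cpg_id = rownames(dataset$betas), dataset$betas,
                    check.names = FALSE, stringsAsFactors = FALSE)
  data.table::fwrite(mat, mpath, sep = "\t")
  data.table::fwrite(dataset$samples, spath, sep = "\t")
  data.table::fwrite(dataset$probes, apath, sep = "\t")
  paths <- c(betas = mpath, samples = spath, probes = apath)
  if (!is.null(dataset$truth)) {
    tpath <- file.path(dir, "truth.json")
    jsonlite::write_json(dataset$truth, tpath, auto_unbox = TRUE, digits = NA)
    paths <- c(paths, truth = tpath)
  }
  invisible(paths)
}

#' Drop CpGs with missing values (complete-case), or impute
#'
#' Marker discovery assumes a complete matrix; by default CpGs with any
#' missing beta are removed. Optionally missing values are replaced by the
#' per-CpG median.
#'
#' @param betas beta matrix.
#' @param impute if TRUE, median-impute instead of dropping.
#' @return a complete beta matrix.
#' @export
handle_missing <- function(betas, impute = FALSE) {
  if (!anyNA(betas)) return(betas)
  if (!impute) return(betas[stats::complete.cases(betas), , drop = FALSE])
  t(apply(betas, 1L, function(r) {
    r[is.na(r)] <- stats::median(r, na.rm = TRUE)
    r
  }))
}
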