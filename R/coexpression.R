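#' Relative expression by the 2^-ddCq method
#'
#' Technical replicates are averaged on the Cq (cycle) scale per
#' (sample, gene); then `dCq = mean Cq(target) - mean Cq(reference)` per
#' sample, `ddCq = dCq(sample) - dCq(calibrator)`, and
#' `rel_expr = 2^-ddCq`. The calibrator sample has `rel_expr == 1` exactly.
#'
#' @param cq Long-format Cq table with columns `sample`, `gene`,
#'   `replicate`, `cq` (e.g. from [simulate_cq_table] or a CSV read with
#'   [data.table::fread]).
#' @param reference_gene Reference (housekeeping) gene used for dCq
#'   normalisation.
#' @param calibrator_sample Sample against which ddCq is computed.
#' @return `data.table` per (sample, target gene): `mean_cq`, `delta_cq`,
#'   `delta_delta_cq`, `rel_expr`. Samples lacking the reference gene are
#'   skipped with a warning.
#' @export
delta_delta_cq <- function(cq,
                           reference_gene = attr(cq, "reference_gene") %||% "NONO",
                           calibrator_sample = attr(cq, "calibrator_sample")) {
  cq <- data.table::as.data.table(cq)
  if (any(cq$cq <= 0)) stopf("Cq values must be positive")
  if (is.null(calibrator_sample)) stopf("calibrator_sample must be given")
  means <- cq[, list(mean_cq = mean(cq)), by = c("sample", "gene")]
  refs <- means[means$gene == reference_gene, ]
  if (!calibrator_sample %in% means$sample)
    stopf("calibrator sample '%s' absent from Cq table", calibrator_sample)
  missing_ref <- setdiff(unique(means$sample), refs$sample)
  if (length(missing_ref)) {
    warnf("sample(s) without reference gene '%s' skipped: %s",
          reference_gene, paste(missing_ref, collapse = ", "))
    means <- means[!means$sample %in% missing_ref, ]
  }
  if (!reference_gene %in% cq$gene[cq$sample == calibrator_sample])
    stopf("reference gene '%s' absent from calibrator sample", reference_gene)
  targets <- means[means$gene != reference_gene, ]
  refmap <- stats::setNames(refs$mean_cq, refs$sample)
  targets$delta_cq <- targets$mean_cq - refmap[targets$sample]
  cal <- targets[targets$sample == calibrator_sample, ]
  calmap <- stats::setNames(cal$delta_cq, cal$gene)
  if (any(!targets$gene %in% names(calmap)))
    stopf("gene(s) absent from calibrator sample: %s",
          paste(setdiff(targets$gene, names(calmap)), collapse = ", "))
  targets$delta_delta_cq <- targets$delta_cq - calmap[targets$gene]
  targets$rel_expr <- 2^(-targets$delta_delta_cq)
  targets
}

#' Tissue-panel relative expression matrix
#'
#' Rescales relative expression per gene so that the highest-expressing
#' tissue equals 1 -- the max-relative normalisation used for
#' tissue-co-expression heatmaps (highest level black, lowest white).
#'
#' @param rel A [delta_delta_cq] result (or any data frame with `sample`,
#'   `gene`, `rel_expr`), where samples are tissues.
#' @return Numeric matrix, genes x tissues, values in (0, 1]; each row's
#'   maximum is 1. Genes with no finite value are dropped with a warning.
#' @export
tissue_relative_matrix <- function(rel) {
  rel <- data.table::as.data.table(rel)
  genes <- unique(rel$gene)
  tissues <- unique(rel$sample)
  m <- matrix(NA_real_, length(genes), length(tissues),
              dimnames = list(genes, tissues))
  for (i in seq_len(nrow(rel))) m[rel$gene[i], rel$sample[i]] <- rel$rel_expr[i]
  dead <- rowSums(is.finite(m)) == 0L
  if (any(dead)) {
    warnf("gene(s) with no finite expression dropped: %s",
          paste(genes[dead], collapse = ", "))
    m <- m[!dead, , drop = FALSE]
  }
  mx <- apply(m, 1L, max, na.rm = TRUE)
  out <- m / mx
  attr(out, "unit") <- "max_relative"
  out
}

.ols_one <- function(x, y, group) {
  ok <- is.finite(x) & is.finite(y)
  x <- x[ok]; y <- y[ok]
  if (length(x) < 3L) stopf("group '%s': fewer than 3 paired finite observations", group)
  if (stats::var(x) == 0) stopf("degenerate predictor: zero variance in x (group '%s')", group)
  fit <- stats::lm(y ~ x)
  sm <- summary(fit)
  r <- stats::cor(x, y)
  data.table::data.table(
    group = group, n = length(x),
    slope = unname(stats::coef(fit)[2L]),
    intercept = unname(stats::coef(fit)[1L]),
    pearson_r = r, r_squared = r^2,
    p_value = unname(sm$coefficients[2L, 4L]))
}

#' Sense/antisense-versus-regulator linear regression
#'
#' Ordinary least squares of one gene's abundance on another's across
#' samples, reporting slope, intercept, Pearson R, R-squared and the
#' two-sided p-value for slope != 0. When `groups` is given (e.g. affected
#' versus unaffected individuals), per-group fits are reported alongside
#' the overall fit.
#'
#' @param m Expression matrix (genes x samples), e.g. logCPM.
#' @param x_gene,y_gene Row names: predictor and response genes.
#' @param groups Optional vector of group labels, one per sample column.
#' @return `data.table`, one row per fitted group (plus `"overall"`).
#' @export
pair_regression <- function(m, x_gene, y_gene, groups = NULL) {
  for (g in c(x_gene, y_gene))
    if (!g %in% rownames(m)) stopf("gene '%s' not in matrix", g)
  x <- as.numeric(m[x_gene, ])
  y <- as.numeric(m[y_gene, ])
  out <- list(.ols_one(x, y, "overall"))
  if (!is.null(groups)) {
    if (length(groups) != ncol(m)) stopf("groups must have one label per sample")
    for (g in unique(groups))
      out[[length(out) + 1L]] <- .ols_one(x[groups == g], y[groups == g], g)
  }
  data.table::rbindlist(out)
}

#' Unpaired Student's t-test between condition groups
#'
#' Thin wrapper for knockdown-versus-control comparisons of expression
#' levels; defaults to a one-tailed test (the convention for directional
#' knockdown hypotheses), switchable to two-sided.
#'
#' @param treated,control Numeric vectors of measurements.
#' @param alternative `"greater"` (treated > control, default), `"less"`,
#'   or `"two.sided"`.
#' @param var.equal Assume equal variances (classic Student test, default
#'   `TRUE`).
#' @return The [stats::t.test] `htest` object.
#' @export
unpaired_ttest <- function(treated, control,
                           alternative = c("greater", "less", "two.sided"),
                           var.equal = TRUE) {
  stats::t.test(treated, control, alternative = match.arg(alternative),
                var.equal = var.equal)
}
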