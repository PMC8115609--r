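#' Arcsine square-root transform
#'
#' Variance-stabilizing transform `asin(sqrt(x))` for relative abundances.
#' Values on the percent scale are divided by 100 first when
#' `percent = TRUE`.
#'
#' @param x abundances in `[0, 1]` (or `[0, 100]` with `percent = TRUE`).
#' @param percent divide by 100 before transforming.
#' @return transformed values in `[0, pi/2]`.
#' @export
arcsin_sqrt <- function(x, percent = FALSE) {
  if (percent) x <- x / 100
  if (any(x < 0 | x > 1, na.rm = TRUE))
    stop("abundance fractions must lie in [0, 1] after scaling")
  asin(sqrt(x))
}

#' Per-feature covariate associations (additive linear models)
#'
#' For every feature, fits an ordinary linear model of the
#' arcsine-square-root transformed relative abundance on the target
#' covariate plus the adjustment covariates (all as fixed effects;
#' categorical covariates enter one-hot against their reference level), and
#' reports the target coefficient with its t-test p-value, BH-corrected
#' across features. The conventional reporting cutoff for these
#' multivariable microbiome association scans is a lenient FDR of 0.25,
#' exposed as the `reported` column. Samples with missing values and
#' zero-variance features are dropped per model (with a message); aliased
#' adjustment columns are dropped by the least-squares fit itself.
#'
#' @param table `abund_table` or features x samples matrix (percent scale).
#' @param metadata sample metadata.
#' @param target covariate of interest (metadata column).
#' @param adjust character vector of adjustment covariate columns.
#' @param reference named list/character of reference levels, e.g.
#'   `c(delivery_mode = "vaginal", feeding = "exclusive_bf")`; effect signs
#'   are oriented against these.
#' @param fdr_report reporting threshold on the q-value (default 0.25).
#' @return data.frame: `feature_id`, `covariate` (target contrast name),
#'   `coefficient`, `std_error`, `p_value`, `q_value`, `n_used`,
#'   `reported`.
#' @export
fit_associations <- function(table, metadata, target = "delivery_mode",
                             adjust = c("study_id", "feeding", "day"),
                             reference = c(delivery_mode = "vaginal",
                                           feeding = "exclusive_bf",
                                           maternal_bmi_class = "normal"),
                             fdr_report = 0.25) {
  vals <- tab_values(table)
  md <- metadata[match(colnames(vals), metadata$sample_id), , drop = FALSE]
  if (any(is.na(md$sample_id))) stop("samples missing from metadata")
  covs <- unique(c(target, adjust))
  if (!all(covs %in% names(md)))
    stop("missing metadata columns: ",
         paste(setdiff(covs, names(md)), collapse = ", "))
  design <- md[covs]
  for (cv in covs) {
    if (is.character(design[[cv]]) || is.logical(design[[cv]])) {
      f <- factor(design[[cv]])
      if (cv %in% names(reference) && reference[[cv]] %in% levels(f))
        f <- stats::relevel(f, ref = reference[[cv]])
      design[[cv]] <- f
    }
  }
  res <- list()
  for (i in seq_len(nrow(vals))) {
    y <- arcsin_sqrt(vals[i, ], percent = TRUE)
    dat <- cbind(data.frame(.y = y), design)
    dat <- dat[stats::complete.cases(dat), , drop = FALSE]
    if (nrow(dat) < length(covs) + 2L) next
    if (stats::var(dat$.y) == 0) {
      message("dropping zero-variance feature ", rownames(vals)[i])
      next
    }
    fml <- stats::as.formula(paste(".y ~", paste(covs, collapse = " + ")))
    fit <- stats::lm(fml, data = dat)
    sm <- summary(fit)$coefficients
    hit <- grep(paste0("^", target), rownames(sm), value = TRUE)
    for (h in hit) {
      res[[length(res) + 1L]] <- data.frame(
        feature_id = rownames(vals)[i], covariate = h,
        coefficient = sm[h, "Estimate"], std_error = sm[h, "Std. Error"],
        p_value = sm[h, "Pr(>|t|)"], n_used = nrow(dat),
        stringsAsFactors = FALSE)
    }
  }
  out <- do.call(rbind, res)
  if (is.null(out)) return(data.frame())
  out$q_value <- bh_fdr(out$p_value)
  out$reported <- out$q_value < fdr_report
  rownames(out) <- NULL
  out
}
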