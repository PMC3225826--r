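# Linear co-regulation model for TF-knockdown expression log-ratios:
#   g_k = c + a_TF * b_TF,k + sum_i a_mir_i * b_mir_i,k + error,
# where g_k is the log expression ratio of gene k after vs before TF
# depletion and b are 0/1 target indicators.  miRNAs are first prescreened
# one at a time (model with intercept + TF + one miRNA), survivors enter a
# bidirectional stepwise-AIC search in which the intercept and the TF term
# are always retained.

#' Construct a knockdown dataset
#'
#' @param gene_ids character vector of gene IDs.
#' @param logratios numeric vector of per-gene expression log-ratios
#'   (after-depletion vs before), aligned with `gene_ids`.
#' @param tf_targets character vector of genes targeted by the depleted TF.
#' @param mirna_targets a [target_map()] of miRNA target genes.
#' @return an object of class `knockdown_dataset` with components
#'   `gene_ids`, `g`, `b_tf` (0/1 vector), `b_mir` (0/1 genes x miRNAs
#'   matrix) and `mirna_ids`.
#' @export
knockdown_dataset <- function(gene_ids, logratios, tf_targets, mirna_targets) {
  stopifnot(inherits(mirna_targets, "target_map"))
  gene_ids <- as.character(gene_ids)
  if (length(logratios) != length(gene_ids)) {
    stop("`logratios` and `gene_ids` must have the same length", call. = FALSE)
  }
  if (anyDuplicated(gene_ids)) {
    stop("duplicate gene IDs in knockdown dataset", call. = FALSE)
  }
  mirna_ids <- sort(names(mirna_targets$entries))
  b_mir <- vapply(mirna_ids, function(m)
    as.numeric(gene_ids %in% mirna_targets$entries[[m]]),
    numeric(length(gene_ids)))
  b_mir <- matrix(b_mir, nrow = length(gene_ids),
                  dimnames = list(gene_ids, mirna_ids))
  structure(list(gene_ids = gene_ids,
                 g = as.numeric(unname(logratios)),
                 b_tf = as.numeric(gene_ids %in% tf_targets),
                 b_mir = b_mir,
                 mirna_ids = mirna_ids),
            class = "knockdown_dataset")
}

#' @export
print.knockdown_dataset <- function(x, ...) {
  cat(sprintf("knockdown_dataset: %d genes (%d TF targets), %d miRNAs\n",
              length(x$gene_ids), sum(x$b_tf), length(x$mirna_ids)))
  invisible(x)
}

kd_frame <- function(data, mirnas) {
  df <- data.frame(g = data$g, tf = data$b_tf)
  for (m in mirnas) df[[paste0("mir_", make.names(m))]] <- data$b_mir[, m]
  df
}

# AIC on the Gaussian-likelihood scale used for model comparison:
# n * log(RSS / n) + 2k, k counting all estimated coefficients.
kd_aic <- function(fit) {
  rss <- sum(fit$residuals^2)
  n <- length(fit$residuals)
  k <- sum(!is.na(coef(fit)))
  n * log(rss / n) + 2 * k
}

#' Single-miRNA prescreen p-value
#'
#' Fits the alternative model with the TF and one miRNA at a time,
#' `g = c + a_TF b_TF + a_mir b_mir + error`, and returns the two-sided
#' t-test p-value of the miRNA coefficient.
#'
#' @param data a [knockdown_dataset()].
#' @param mirna_id one of `data$mirna_ids`.
#' @return numeric p-value, or `NA` (with a warning) when the design is
#'   rank-deficient, e.g. the miRNA targets none or all of the genes.
#' @export
prescreen_mirna <- function(data, mirna_id) {
  stopifnot(inherits(data, "knockdown_dataset"))
  if (!mirna_id %in% data$mirna_ids) {
    stop(sprintf("unknown miRNA '%s'", mirna_id), call. = FALSE)
  }
  df <- kd_frame(data, mirna_id)
  fit <- lm(g ~ ., data = df)
  cf <- summary(fit)$coefficients
  term <- paste0("mir_", make.names(mirna_id))
  if (anyNA(coef(fit)) || !term %in% rownames(cf)) {
    warning(sprintf("miRNA '%s': rank-deficient design; excluded", mirna_id),
            call. = FALSE)
    return(NA_real_)
  }
  unname(cf[term, "Pr(>|t|)"])
}

#' Fit the full co-regulation model for a given miRNA subset
#'
#' Ordinary least squares of the log-ratios on the intercept, the TF
#' indicator, and the indicators of the given miRNAs; effects are shared
#' across genes.
#'
#' @param data a [knockdown_dataset()].
#' @param mirna_subset character vector of miRNA IDs (may be empty for the
#'   TF-only model).
#' @return an object of class `knockdown_fit`: list with `intercept`,
#'   `a_tf`, `a_mir` (named vector), `coefficients` table (estimate, SE,
#'   t, p), `aic`, `selected`, and the underlying `lm` fit.
#' @export
fit_full_model <- function(data, mirna_subset = character(0)) {
  stopifnot(inherits(data, "knockdown_dataset"))
  mirna_subset <- as.character(mirna_subset)
  bad <- setdiff(mirna_subset, data$mirna_ids)
  if (length(bad) > 0L) {
    stop(sprintf("unknown miRNA(s): %s", paste(bad, collapse = ", ")),
         call. = FALSE)
  }
  df <- kd_frame(data, mirna_subset)
  fit <- lm(g ~ ., data = df)
  cf <- summary(fit)$coefficients
  terms_mir <- paste0("mir_", make.names(mirna_subset))
  a_mir <- setNames(rep(NA_real_, length(mirna_subset)), mirna_subset)
  hit <- terms_mir %in% rownames(cf)
  a_mir[hit] <- cf[terms_mir[hit], "Estimate"]
  structure(list(intercept = unname(cf["(Intercept)", "Estimate"]),
                 a_tf = if ("tf" %in% rownames(cf))
                   unname(cf["tf", "Estimate"]) else NA_real_,
                 a_mir = a_mir,
                 coefficients = cf,
                 aic = kd_aic(fit),
                 selected = mirna_subset,
                 lm_fit = fit),
            class = "knockdown_fit")
}

#' Select co-regulating miRNAs by prescreen plus stepwise AIC
#'
#' Candidates are first filtered by the single-miRNA prescreen
#' (`p < prescreen_alpha`); the survivors then enter a bidirectional
#' stepwise search over miRNA terms that minimizes
#' `AIC = n log(RSS/n) + 2k`, with the intercept and the TF term always
#' kept.  The final model is refit and returned.
#'
#' @param data a [knockdown_dataset()].
#' @param candidate_mirnas miRNA IDs to consider (default: all in `data`).
#' @param prescreen_alpha prescreen significance threshold (default 0.05).
#' @return a `knockdown_fit` (see [fit_full_model()]) whose `selected`
#'   component lists the chosen miRNAs; also carries `prescreen`
#'   (named p-value vector) and `survivors` attributes.
#' @export
select_mirna_regulators <- function(data, candidate_mirnas = data$mirna_ids,
                                    prescreen_alpha = 0.05) {
  stopifnot(inherits(data, "knockdown_dataset"))
  if (length(data$gene_ids) < 2L) stop("need at least 2 genes", call. = FALSE)
  if (length(candidate_mirnas) == 0L) stop("no candidate miRNAs", call. = FALSE)
  pre <- vapply(candidate_mirnas, function(m)
    suppressWarnings(prescreen_mirna(data, m)), numeric(1L))
  names(pre) <- candidate_mirnas
  survivors <- candidate_mirnas[!is.na(pre) & pre < prescreen_alpha]
  if (length(survivors) == 0L) {
    res <- fit_full_model(data, character(0))
  } else {
    df <- kd_frame(data, survivors)
    base_fit <- lm(g ~ tf, data = df)
    upper <- as.formula(paste("~ tf +", paste(
      paste0("mir_", make.names(survivors)), collapse = " + ")))
    stepped <- step(base_fit, scope = list(lower = ~tf, upper = upper),
                    direction = "both", trace = 0)
    kept_terms <- attr(stepped$terms, "term.labels")
    kept <- survivors[paste0("mir_", make.names(survivors)) %in% kept_terms]
    res <- fit_full_model(data, kept)
  }
  attr(res, "prescreen") <- pre
  attr(res, "survivors") <- survivors
  res
}

#' @export
print.knockdown_fit <- function(x, ...) {
  cat(sprintf("knockdown co-regulation model: %d miRNA(s) selected\n",
              length(x$selected)))
  cat(sprintf("  intercept c = %.4f, TF effect a_TF = %.4f, AIC = %.2f\n",
              x$intercept, x$a_tf, x$aic))
  if (length(x$selected) > 0L) {
    cat("  miRNA effects:\n")
    for (m in x$selected) {
      cat(sprintf("    %-12s a = %+.4f\n", m, x$a_mir[[m]]))
    }
  }
  invisible(x)
}

#' @export
summary.knockdown_fit <- function(object, ...) {
  print(object)
  cat("\nCoefficient table:\n")
  print(object$coefficients)
  invisible(object)
}

#' @export
coef.knockdown_fit <- function(object, ...) {
  c(intercept = object$intercept, a_tf = object$a_tf, object$a_mir)
}

#' @export
residuals.knockdown_fit <- function(object, ...) residuals(object$lm_fit)

#' @export
predict.knockdown_fit <- function(object, ...) predict(object$lm_fit, ...)
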