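# Shared design preparation: drop constant columns, then exactly collinear
# ones (QR pivoting against the intercept-augmented design).
.prepare_design <- function(X, n, max_cols = NULL) {
  if (is.null(colnames(X)) && ncol(X) > 0)
    colnames(X) <- sprintf("x%d", seq_len(ncol(X)))
  dropped <- character(0)
  if (ncol(X) > 0) {
    const <- apply(X, 2, function(v) max(v) == min(v))
    dropped <- colnames(X)[const]
    X <- X[, !const, drop = FALSE]
  }
  if (!is.null(max_cols) && ncol(X) > max_cols)
    stop("rank deficiency: ", ncol(X), " non-constant predictors for ",
         n, " patients; reduce the landscape or pool enhancers ",
         "(at most patients - 1 predictors are identifiable)")
  if (ncol(X) > 0) {
    qr_d <- qr(cbind(`(Intercept)` = 1, X))
    keep_piv <- qr_d$pivot[seq_len(qr_d$rank)]
    coll <- setdiff(seq_len(ncol(X)) + 1L, keep_piv)
    if (length(coll) > 0) {
      dropped <- c(dropped, colnames(X)[coll - 1L])
      X <- X[, -(coll - 1L), drop = FALSE]
    }
  }
  list(X = X, dropped = dropped)
}

#' Fit a per-gene Gaussian GLM of expression on enhancer occupancy
#'
#' Models a gene's expression across patients as a linear combination of
#' the `log(score + 1)` occupancy values of the enhancers in its
#' landscape (identity link, Gaussian errors, with intercept). Constant
#' and exactly collinear predictor columns are dropped and reported.
#' Per-coefficient two-sided p-values come from the estimate /
#' standard-error t ratio; the model-level p-value is the overall F test
#' against the intercept-only model. Leverage and Cook's distance are
#' returned so linearity and single-point influence can be checked.
#'
#' @param X Numeric patients x enhancers matrix of occupancy scores
#'   (`log(score + 1)`, 0 when absent), columns named by site id.
#' @param y Numeric expression vector, one value per patient.
#' @param gene_id Optional gene identifier carried into the result.
#' @return An object of class `glm_result`: list with `gene_id`,
#'   `coefficients` (incl. intercept), `interactor_p` (named, per retained
#'   enhancer), `model_p`, `dropped_columns`, `fit` (the `glm` object),
#'   `leverage`, `influence`.
#' @export
fit_gene_glm <- function(X, y, gene_id = NULL) {
  X <- as.matrix(X)
  stopifnot(is.numeric(y))
  n <- length(y)
  if (nrow(X) != n) stop("nrow(X) must equal length(y)")
  if (n < 3) stop("need at least 3 patients")
  if (anyNA(y) || any(!is.finite(y))) stop("y must be finite")
  prep <- .prepare_design(X, n, max_cols = n - 1L)
  Xk <- prep$X
  df <- data.frame(.expr = y, Xk, check.names = FALSE)
  form <- if (ncol(Xk) > 0)
    stats::reformulate(sprintf("`%s`", colnames(Xk)), response = ".expr")
  else stats::as.formula(".expr ~ 1")
  fit <- stats::glm(form, data = df, family = stats::gaussian())
  sm <- summary(fit)$coefficients
  coefs <- stats::coef(fit)
  inter_p <- if (ncol(Xk) > 0) {
    p <- sm[-1L, 4L]
    stats::setNames(as.numeric(p), colnames(Xk))
  } else stats::setNames(numeric(0), character(0))
  model_p <- NA_real_
  if (ncol(Xk) > 0 && n - ncol(Xk) - 1L > 0) {
    rss1 <- sum(stats::residuals(fit)^2)
    rss0 <- sum((y - mean(y))^2)
    f <- ((rss0 - rss1) / ncol(Xk)) / (rss1 / (n - ncol(Xk) - 1L))
    model_p <- stats::pf(f, ncol(Xk), n - ncol(Xk) - 1L,
                         lower.tail = FALSE)
  }
  structure(list(
    gene_id = gene_id, coefficients = coefs, interactor_p = inter_p,
    model_p = model_p, dropped_columns = prep$dropped, fit = fit,
    leverage = stats::hatvalues(fit),
    influence = stats::cooks.distance(fit)
  ), class = "glm_result")
}

#' @export
print.glm_result <- function(x, ...) {
  cat("glm_result", if (!is.null(x$gene_id)) paste0("[", x$gene_id, "]"),
      ":", length(x$interactor_p), "enhancer(s), model p =",
      format(x$model_p, digits = 3), "\n")
  invisible(x)
}

#' Permutation likelihood-ratio p-values for the occupancy GLM
#'
#' Empirical p-values by permutation, `p = (1 + #\{LR_perm >= LR_obs\}) /
#' (1 + n_perm)`. Two modes:
#' \describe{
#'   \item{model}{LR statistic of the full model against the
#'     intercept-only model; the response is permuted.}
#'   \item{interactor}{For each retained enhancer j, LR of the full model
#'     against the model without j; the covariate is residualized on the
#'     remaining design and those residuals are permuted (conditional
#'     permutation, as in permutation-of-regressor GLM inference), so the
#'     other enhancers' association structure is preserved.}
#' }
#'
#' @param X Patients x enhancers occupancy matrix.
#' @param y Expression vector.
#' @param n_perm Number of permutations (default 1000).
#' @param mode `"interactor"` (default) or `"model"`.
#' @param seed Optional RNG seed; fixed seed gives identical p-values.
#' @return For `mode = "model"` a single numeric p-value; for
#'   `mode = "interactor"` a named vector, one p per retained enhancer.
#' @export
permutation_pvalue <- function(X, y, n_perm = 1000L,
                               mode = c("interactor", "model"),
                               seed = NULL) {
  mode <- match.arg(mode)
  if (n_perm < 1) stop("n_perm must be >= 1")
  X <- as.matrix(X)
  n <- length(y)
  stopifnot(nrow(X) == n)
  prep <- .prepare_design(X, n, max_cols = n - 1L)
  Xk <- prep$X
  if (ncol(Xk) == 0) stop("no non-constant predictors to test")
  if (!is.null(seed)) set.seed(seed)
  lr <- function(rss0, rss1) n * log(rss0 / rss1)

  if (mode == "model") {
    qr_full <- qr(cbind(1, Xk))
    rss0 <- sum((y - mean(y))^2)        # invariant under permutation
    rss1 <- sum(qr.resid(qr_full, y)^2)
    obs <- lr(rss0, rss1)
    perm <- vapply(seq_len(n_perm), function(i) {
      yp <- y[sample.int(n)]
      lr(rss0, sum(qr.resid(qr_full, yp)^2))
    }, numeric(1))
    return((1 + sum(perm >= obs)) / (1 + n_perm))
  }

  out <- stats::setNames(numeric(ncol(Xk)), colnames(Xk))
  for (j in seq_len(ncol(Xk))) {
    red <- cbind(1, Xk[, -j, drop = FALSE])
    qr_red <- qr(red)
    rss_red <- sum(qr.resid(qr_red, y)^2)
    y_r <- qr.resid(qr_red, y)
    z <- qr.resid(qr_red, Xk[, j])      # residualized covariate
    impr <- function(zz) {
      zp <- qr.resid(qr_red, zz)        # re-orthogonalize permuted z
      zz2 <- sum(zp^2)
      if (zz2 < 1e-12) return(0)
      sum(zp * y_r)^2 / zz2
    }
    obs <- lr(rss_red, rss_red - impr(z))
    perm <- vapply(seq_len(n_perm), function(i)
      lr(rss_red, rss_red - impr(z[sample.int(n)])), numeric(1))
    out[j] <- (1 + sum(perm >= obs)) / (1 + n_perm)
  }
  out
}

#' Genome-wide occupancy-expression scan
#'
#' Fits the occupancy GLM for every gene with a nonempty enhancer
#' landscape and collects (enhancer, gene) pairs whose interactor p-value
#' falls below `alpha`. Genes are fitted independently, so results do not
#' depend on processing order. The default `alpha = 0.001` is used on raw
#' p-values; Benjamini-Hochberg adjustment is available behind
#' `adjust = "BH"`.
#'
#' @param landscapes Named list of landscapes from
#'   [build_gene_landscapes()].
#' @param universe The `site_universe` providing the occupancy matrix.
#' @param expression Genes x patients numeric matrix; column names must
#'   match the universe's patient ids exactly (any order).
#' @param alpha Significance cutoff on interactor p-values.
#' @param adjust `"none"` (default) or `"BH"`.
#' @return List with `results` (all fitted pairs: `gene_id, site_id,
#'   prevalence, coefficient, interactor_p, model_p`), `significant`
#'   (rows passing `alpha`), `n_significant_sites`, `n_significant_genes`.
#' @export
genome_scan <- function(landscapes, universe, expression, alpha = 0.001,
                        adjust = c("none", "BH")) {
  adjust <- match.arg(adjust)
  stopifnot(inherits(universe, "site_universe"), is.matrix(expression))
  patients <- rownames(universe$occurrence)
  missing_pat <- setdiff(patients, colnames(expression))
  extra_pat <- setdiff(colnames(expression), patients)
  if (length(missing_pat) > 0 || length(extra_pat) > 0)
    stop("patient mismatch between peak sets and expression; missing: [",
         paste(missing_pat, collapse = ", "), "], unmatched: [",
         paste(extra_pat, collapse = ", "), "]")
  genes <- sort(intersect(names(landscapes), rownames(expression)))
  rows <- list()
  for (g in genes) {
    ls <- landscapes[[g]]
    if (nrow(ls) == 0L) next
    Xg <- universe$occurrence[patients, ls$site_id, drop = FALSE]
    fit <- tryCatch(fit_gene_glm(Xg, expression[g, patients], gene_id = g),
                    error = function(e) NULL)
    if (is.null(fit) || length(fit$interactor_p) == 0L) next
    sid <- names(fit$interactor_p)
    prev <- ls$prevalence[match(sid, ls$site_id)]
    rows[[g]] <- data.frame(
      gene_id = g, site_id = sid, prevalence = prev,
      coefficient = unname(fit$coefficients[-1L][sid]),
      interactor_p = unname(fit$interactor_p),
      model_p = fit$model_p, stringsAsFactors = FALSE)
  }
  res <- if (length(rows) > 0) do.call(rbind, rows) else
    data.frame(gene_id = character(0), site_id = character(0),
               prevalence = integer(0), coefficient = numeric(0),
               interactor_p = numeric(0), model_p = numeric(0),
               stringsAsFactors = FALSE)
  rownames(res) <- NULL
  pcol <- res$interactor_p
  if (adjust == "BH" && nrow(res) > 0)
    pcol <- stats::p.adjust(pcol, method = "BH")
  res$p_used <- pcol
  sig <- res[!is.na(pcol) & pcol < alpha, , drop = FALSE]
  list(results = res, significant = sig,
       n_significant_sites = length(unique(sig$site_id)),
       n_significant_genes = length(unique(sig$gene_id)))
}
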