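# Elastic-net stability selection with permutation p-values and
# Benjamini-Hochberg FDR assessment.

#' Build the model design matrix
#'
#' Standardizes the 11 ln-scale metal columns and the adjustment
#' covariates (all independent variables are standardized), and
#' optionally adds the two-way interaction block: all 55 metal-metal
#' products plus metal-by-sex and metal-by-education products, each the
#' product of its standardized parents. Adjustment covariates are never
#' penalized; metals and interaction terms are.
#'
#' @param data One completed (imputed) dataset with ln-scale metals.
#' @param include_interactions Add the 77 interaction columns.
#' @param modifiers Effect-measure modifiers crossed with the metals.
#' @return List of class `cp_design`: `x` (matrix), `y`, `terms`,
#'   `penalized` (logical per column), `center`, `scale`.
#' @export
build_design <- function(data, include_interactions = FALSE,
                         modifiers = c("sex", "education")) {
  vars <- c(METALS, ADJUST_COVARIATES)
  miss <- vars[!vars %in% names(data)]
  if (length(miss)) abort("design needs columns: %s", paste(miss, collapse = ", "))
  if (anyNA(data[, vars])) abort("design input has missing cells; impute first")
  X <- as.matrix(data[, vars, drop = FALSE])
  ctr <- colMeans(X)
  scl <- apply(X, 2L, stats::sd)
  if (any(scl == 0)) abort("constant column(s): %s",
                           paste(vars[scl == 0], collapse = ", "))
  Xs <- sweep(sweep(X, 2L, ctr), 2L, scl, "/")
  penalized <- vars %in% METALS
  if (include_interactions) {
    pairs <- utils::combn(METALS, 2L)
    inter <- matrix(NA_real_, nrow(Xs), ncol(pairs) +
                      length(METALS) * length(modifiers))
    nm <- character(ncol(inter))
    for (j in seq_len(ncol(pairs))) {
      inter[, j] <- Xs[, pairs[1, j]] * Xs[, pairs[2, j]]
      nm[j] <- paste0(pairs[1, j], ":", pairs[2, j])
    }
    k <- ncol(pairs)
    for (mod in modifiers) for (met in METALS) {
      k <- k + 1L
      inter[, k] <- Xs[, met] * Xs[, mod]
      nm[k] <- paste0(met, ":", mod)
    }
    colnames(inter) <- nm
    Xs <- cbind(Xs, inter)
    penalized <- c(penalized, rep(TRUE, ncol(inter)))
  }
  structure(list(x = Xs, y = data$case, terms = colnames(Xs),
                 penalized = penalized, center = ctr, scale = scl),
            class = "cp_design")
}

#' Penalized logistic elastic net with unpenalized covariates
#'
#' Fits a logistic elastic net (mixing parameter `alpha`) in which the
#' adjustment covariates carry no penalty. Lambda is chosen by k-fold
#' cross-validated deviance (lambda.min) unless a fixed `lambda` is
#' supplied. A penalized term is selected iff its coefficient is nonzero
#' at the chosen lambda.
#'
#' @param design A `cp_design` from [build_design()].
#' @param alpha Elastic-net mixing parameter (default 0.9).
#' @param lambda `NULL` for CV choice, or a fixed value (0 gives the
#'   unpenalized MLE).
#' @param nfolds,nlambda CV controls.
#' @param seed Seed fixing the CV fold assignment.
#' @param fold_groups Optional grouping vector (one entry per row): rows
#'   sharing a group are assigned to the same CV fold. Used on bootstrap
#'   resamples, where duplicated subjects split across folds would leak
#'   into the held-out deviance and bias lambda low.
#' @param lambda_min_ratio Smallest lambda as a fraction of the largest.
#' @return List: `coef` (named, with intercept), `selected` (logical over
#'   penalized terms), `lambda`, `separation` flag.
#' @export
elastic_net_logistic <- function(design, alpha = 0.9, lambda = NULL,
                                 nfolds = 5L, nlambda = 30L, seed = 1L,
                                 fold_groups = NULL,
                                 lambda_min_ratio = 0.05) {
  x <- design$x; y <- design$y
  if (any(apply(x, 2L, function(v) all(v == v[1]))))
    abort("design contains a constant column")
  pf <- as.numeric(design$penalized)
  if (is.null(lambda)) {
    fit <- glmnet::glmnet(x, y, family = "binomial", alpha = alpha,
                          penalty.factor = pf, standardize = FALSE,
                          nlambda = nlambda,
                          lambda.min.ratio = lambda_min_ratio)
    lams <- fit$lambda
    set.seed(as.integer(seed))
    if (is.null(fold_groups)) {
      foldid <- sample(rep(seq_len(nfolds), length.out = length(y)))
    } else {
      ug <- unique(fold_groups)
      gf <- sample(rep(seq_len(nfolds), length.out = length(ug)))
      foldid <- gf[match(fold_groups, ug)]
    }
    dev <- matrix(NA_real_, nfolds, length(lams))
    for (f in seq_len(nfolds)) {
      tr <- foldid != f
      ff <- glmnet::glmnet(x[tr, , drop = FALSE], y[tr],
                           family = "binomial", alpha = alpha,
                           penalty.factor = pf, standardize = FALSE,
                           lambda = lams)
      mu <- stats::plogis(stats::predict(ff, x[!tr, , drop = FALSE]))
      mu <- pmin(pmax(mu, 1e-10), 1 - 1e-10)
      dev[f, seq_len(ncol(mu))] <-
        -2 * colSums(y[!tr] * log(mu) + (1 - y[!tr]) * log(1 - mu))
    }
    lam <- lams[which.min(colMeans(dev, na.rm = TRUE))]
    co <- as.numeric(stats::coef(fit, s = lam, exact = FALSE))
  } else {
    path <- sort(unique(c(lambda, lambda + c(0.5, 0.1, 0.05, 0.01))),
                 decreasing = TRUE)
    fit <- glmnet::glmnet(x, y, family = "binomial", alpha = alpha,
                          penalty.factor = pf, standardize = FALSE,
                          lambda = path, thresh = 1e-12, maxit = 1e6)
    lam <- lambda
    co <- as.numeric(stats::coef(fit, s = lambda, exact = FALSE))
  }
  names(co) <- c("(Intercept)", design$terms)
  beta <- co[-1]
  list(coef = co,
       selected = beta[design$penalized] != 0,
       lambda = lam,
       separation = any(abs(beta) > 20))
}

# stratified case/control resample preserving the case count; bounds are
# expanded to follow duplicated rows
resample_stratified <- function(data, bounds, seed, min_cases = 5L) {
  set.seed(as.integer(seed))
  cases <- which(data$case == 1)
  controls <- which(data$case == 0)
  for (try in 1:100) {
    idx <- c(sample(cases, length(cases), replace = TRUE),
             sample(controls, length(controls), replace = TRUE))
    if (sum(data$case[idx]) >= min_cases) break
  }
  new <- data[idx, , drop = FALSE]
  old_id <- new$subject_id
  new$subject_id <- seq_len(nrow(new))
  rownames(new) <- NULL
  attr(new, "orig_id") <- old_id
  new_bounds <- NULL
  if (!is.null(bounds) && nrow(bounds)) {
    hit <- lapply(seq_len(nrow(new)), function(i) {
      b <- bounds[bounds$subject_id == old_id[i], , drop = FALSE]
      if (nrow(b)) { b$subject_id <- new$subject_id[i]; b } else NULL
    })
    new_bounds <- do.call(rbind, hit)
  }
  list(data = new, bounds = new_bounds)
}

# selection indicator for each penalized term in one completed dataset;
# CV folds are grouped by original subject so bootstrap duplicates never
# straddle a fold boundary
fit_selection <- function(dataset, include_interactions, modifiers, alpha,
                          nfolds, nlambda, seed, fold_groups = NULL) {
  design <- build_design(dataset, include_interactions, modifiers)
  elastic_net_logistic(design, alpha = alpha, nfolds = nfolds,
                       nlambda = nlambda, seed = seed,
                       fold_groups = fold_groups)$selected
}

#' Stability selection over bootstrap resamples and imputations
#'
#' For each of `B` stratified row-resamples (cases and controls drawn
#' with replacement separately, preserving the case count), `M` imputed
#' datasets are generated and the elastic net is run in each; the
#' per-resample selection frequency of a term is the fraction of the M
#' datasets selecting it, and the reported selection probability `P_sel`
#' is the mean over the B resamples. Complete data make the M imputed
#' copies identical, so a single fit per resample is used.
#'
#' @param data Preprocessed analytic table (ln-scale metals; `case`,
#'   `subject_id` columns), possibly with missing cells.
#' @param B Number of resamples (>= 2).
#' @param M Imputations per resample (>= 2).
#' @param alpha Elastic-net mixing parameter.
#' @param seed Integer seed; the whole procedure is reproducible.
#' @param bounds Censoring bounds passed to [impute()].
#' @param include_interactions,modifiers Design options
#'   (see [build_design()]).
#' @param nfolds,nlambda CV controls per elastic-net fit.
#' @return Named numeric vector of selection probabilities over the
#'   penalized terms, with attributes `B`, `M`, `failures`.
#' @export
stability_selection <- function(data, B = 200L, M = 20L, alpha = 0.9,
                                seed = 1L, bounds = NULL,
                                include_interactions = FALSE,
                                modifiers = c("sex", "education"),
                                nfolds = 5L, nlambda = 30L) {
  if (B < 2 || M < 2) abort("B and M must be at least 2")
  used <- intersect(imputation_variables(), names(data))
  complete <- !anyNA(data[, used])
  seeds <- derive_seeds(seed, 2L * B)
  psel <- NULL
  failures <- 0L
  for (b in seq_len(B)) {
    rs <- resample_stratified(data, bounds, seeds[b])
    groups <- attr(rs$data, "orig_id")
    freq <- tryCatch({
      if (complete) {
        sel <- fit_selection(rs$data, include_interactions, modifiers,
                             alpha, nfolds, nlambda, seeds[B + b], groups)
        as.numeric(sel)
      } else {
        imp <- impute(rs$data, M = M, bounds = rs$bounds, seed = seeds[B + b])
        sels <- vapply(seq_len(M), function(m)
          as.numeric(fit_selection(imp$datasets[[m]], include_interactions,
                                   modifiers, alpha, nfolds, nlambda,
                                   seeds[B + b] + m, groups)),
          numeric(count_penalized(include_interactions, modifiers)))
        rowMeans(sels)
      }
    }, error = function(e) { NULL })
    if (is.null(freq)) { failures <- failures + 1L; next }
    psel <- if (is.null(psel)) freq else psel + freq
  }
  eff_B <- B - failures
  if (eff_B == 0) abort("all stability-selection resamples failed")
  out <- psel / eff_B
  names(out) <- penalized_term_names(include_interactions, modifiers)
  attr(out, "B") <- B; attr(out, "M") <- M; attr(out, "failures") <- failures
  out
}

penalized_term_names <- function(include_interactions, modifiers) {
  nm <- METALS
  if (include_interactions) {
    pairs <- utils::combn(METALS, 2L)
    nm <- c(nm, paste0(pairs[1, ], ":", pairs[2, ]),
            unlist(lapply(modifiers, function(mod) paste0(METALS, ":", mod))))
  }
  nm
}

count_penalized <- function(include_interactions, modifiers)
  length(penalized_term_names(include_interactions, modifiers))

#' Permutation p-values for stability selection
#'
#' Permutes the case labels against the full design `K` times, reruns a
#' reduced stability selection on each permuted dataset, and computes
#' each term's p-value as `(1 + #{null P_sel >= observed P_sel}) /
#' (1 + K)`.
#'
#' @inheritParams stability_selection
#' @param K Number of permutations (>= 19).
#' @param B_perm,M_perm Reduced resample/imputation counts for the null
#'   runs.
#' @param observed_psel Observed selection probabilities from
#'   [stability_selection()].
#' @return Data.frame: `term`, `p_sel`, `p_perm`, plus the null matrix as
#'   attribute `null_psel`.
#' @export
permutation_pvalues <- function(data, observed_psel, K = 1200L,
                                B_perm = 20L, M_perm = 10L, alpha = 0.9,
                                seed = 1L, bounds = NULL,
                                include_interactions = FALSE,
                                modifiers = c("sex", "education"),
                                nfolds = 5L, nlambda = 30L) {
  if (K < 19) abort("K must be at least 19")
  seeds <- derive_seeds(seed, 2L * K)
  null_mat <- matrix(NA_real_, length(observed_psel), K,
                     dimnames = list(names(observed_psel), NULL))
  for (k in seq_len(K)) {
    set.seed(seeds[k])
    perm <- data
    perm$case <- sample(perm$case)
    null_mat[, k] <- stability_selection(
      perm, B = B_perm, M = M_perm, alpha = alpha, seed = seeds[K + k],
      bounds = bounds, include_interactions = include_interactions,
      modifiers = modifiers, nfolds = nfolds, nlambda = nlambda)
  }
  p <- (1 + rowSums(null_mat >= observed_psel)) / (1 + K)
  out <- data.frame(term = names(observed_psel),
                    p_sel = as.numeric(observed_psel),
                    p_perm = as.numeric(p), stringsAsFactors = FALSE)
  attr(out, "null_psel") <- null_mat
  out
}

#' Benjamini-Hochberg step-up thresholds
#'
#' Sorts the p-values ascending, computes thresholds `i * alpha / m`,
#' and passes every p-value at or below the largest rank whose p-value
#' does not exceed its threshold.
#'
#' @param pvalues Numeric vector in (0, 1].
#' @param fdr_alpha FDR level.
#' @return Data.frame in input order: `p`, `bh_threshold`, `pass`.
#' @export
bh_thresholds <- function(pvalues, fdr_alpha = 0.05) {
  if (any(pvalues <= 0 | pvalues > 1)) abort("p-values must lie in (0, 1]")
  m <- length(pvalues)
  o <- order(pvalues)
  thr <- seq_len(m) * fdr_alpha / m
  ok <- pvalues[o] <= thr
  kmax <- if (any(ok)) max(which(ok)) else 0L
  pass <- logical(m)
  pass[o[seq_len(kmax)]] <- TRUE
  data.frame(p = pvalues, bh_threshold = thr[order(o)], pass = pass)
}

#' Full exposure-selection run
#'
#' Orchestrates stability selection, permutation p-values and BH
#' thresholds into a selection report. An exposure is selected when its
#' permutation p-value is at or below `p_cut` and its selection
#' probability exceeds `psel_cut` (defaults: main-effects run p <= 0.05
#' and P_sel > 0.6; the interaction run uses p <= 0.1).
#'
#' @inheritParams stability_selection
#' @inheritParams permutation_pvalues
#' @param p_cut,psel_cut Selection rule.
#' @param fdr_alpha BH level for the multiplicity assessment.
#' @return Data.frame of class `cp_selection_report`: `term`, `p_sel`,
#'   `p_perm`, `bh_threshold`, `bh_pass`, `selected`.
#' @export
select_exposures <- function(data, B = 200L, M = 20L, K = 1200L,
                             B_perm = 20L, M_perm = 10L, alpha = 0.9,
                             seed = 1L, bounds = NULL,
                             include_interactions = FALSE,
                             modifiers = c("sex", "education"),
                             p_cut = if (include_interactions) 0.1 else 0.05,
                             psel_cut = 0.6,
                             fdr_alpha = if (include_interactions) 0.1 else 0.05,
                             nfolds = 5L, nlambda = 30L) {
  seeds <- derive_seeds(seed, 2L)
  psel <- stability_selection(data, B = B, M = M, alpha = alpha,
                              seed = seeds[1], bounds = bounds,
                              include_interactions = include_interactions,
                              modifiers = modifiers, nfolds = nfolds,
                              nlambda = nlambda)
  pp <- permutation_pvalues(data, psel, K = K, B_perm = B_perm,
                            M_perm = M_perm, alpha = alpha, seed = seeds[2],
                            bounds = bounds,
                            include_interactions = include_interactions,
                            modifiers = modifiers, nfolds = nfolds,
                            nlambda = nlambda)
  bh <- bh_thresholds(pp$p_perm, fdr_alpha)
  out <- data.frame(term = pp$term, p_sel = pp$p_sel, p_perm = pp$p_perm,
                    bh_threshold = bh$bh_threshold, bh_pass = bh$pass,
                    selected = pp$p_perm <= p_cut & pp$p_sel > psel_cut,
                    stringsAsFactors = FALSE)
  class(out) <- c("cp_selection_report", "data.frame")
  attr(out, "config") <- list(B = B, M = M, K = K, B_perm = B_perm,
                              M_perm = M_perm, alpha = alpha, seed = seed,
                              p_cut = p_cut, psel_cut = psel_cut,
                              fdr_alpha = fdr_alpha)
  out
}
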