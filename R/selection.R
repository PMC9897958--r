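#' Model term and specification constructors
#'
#' A step-selection model specification is a list of terms, each naming a
#' design-table covariate, its functional form (`"linear"`, `"quadratic"`
#' giving `z` and `z^2`, or `"ln"`), and its kind, which fixes the log
#' offset: distances use `ln(z + 1)` (meters, zero on-feature) and
#' dissimilarities use `ln(max(z, 1e-12))`.  The step-length covariate `sl`
#' is always appended as a linear term.
#'
#' @param var design-table column name.
#' @param form `"linear"`, `"quadratic"`, or `"ln"`.
#' @param kind `"distance"`, `"dissimilarity"`, or `"other"`.
#' @return a `ssf_term` list.
#' @export
ssf_term <- function(var, form = c("linear", "quadratic", "ln"),
                     kind = c("distance", "dissimilarity", "other")) {
  structure(list(var = var, form = match.arg(form), kind = match.arg(kind)),
            class = "ssf_term")
}

term_columns <- function(z, term) {
  switch(term$form,
         linear = setNames(list(z), term$var),
         quadratic = setNames(list(z, z^2),
                              c(term$var, paste0(term$var, "_sq"))),
         ln = setNames(list(
           if (term$kind == "dissimilarity") log(pmax(z, 1e-12))
           else log(z + 1)), paste0("ln_", term$var)))
}

#' Build the model matrix for a specification
#'
#' @param design step design data.frame (`stratum`, `case`, `sl`, covariate
#'   columns).
#' @param terms list of [ssf_term]s.
#' @param step_length include the step-length column (default TRUE).
#' @return numeric matrix with named columns; attribute `"term_map"` maps
#'   each term index to its column names.
#' @export
ssf_model_matrix <- function(design, terms, step_length = TRUE) {
  cols <- list()
  tmap <- list()
  for (i in seq_along(terms)) {
    tc <- term_columns(design[[terms[[i]]$var]], terms[[i]])
    tmap[[i]] <- names(tc)
    cols <- c(cols, tc)
  }
  if (step_length) cols$step_length <- design$sl
  X <- do.call(cbind, cols)
  attr(X, "term_map") <- tmap
  X
}

fit_spec <- function(design, terms, step_length = TRUE) {
  X <- ssf_model_matrix(design, terms, step_length)
  fit <- clr_fit(X, design$stratum, design$case)
  fit$terms <- terms
  fit
}

#' Tier 1: choose the functional form of each covariate
#'
#' Fits single-covariate models (plus step length) under the linear,
#' quadratic and natural-log forms and retains the lowest-AICc form; ties
#' break toward fewer parameters, then the linear form.
#'
#' @param design step design data.frame.
#' @param covariates covariate column names.
#' @param kind covariate kind (shared), see [ssf_term()].
#' @return named character vector of chosen forms, with the AICc
#'   comparison in `attr(, "table")`.
#' @export
tier1_select_forms <- function(design, covariates, kind = "distance") {
  forms <- c("linear", "ln", "quadratic")  # tie-break preference order
  tab <- list()
  chosen <- character(0)
  for (v in covariates) {
    fits <- lapply(forms, function(f) {
      tryCatch(fit_spec(design, list(ssf_term(v, f, kind))),
               error = function(e) NULL)
    })
    ok <- !vapply(fits, is.null, TRUE)
    if (!any(ok)) stop("no functional form fit for ", v)
    a <- vapply(fits[ok], function(f) f$aicc, 0)
    k <- vapply(fits[ok], function(f) f$k, 0)
    ord <- order(round(a, 10), k, seq_along(a))
    chosen[v] <- forms[ok][ord[1]]
    tab[[v]] <- data.frame(covariate = v, form = forms[ok], aicc = a, k = k)
  }
  structure(chosen, table = do.call(rbind, tab))
}

#' Tier 2: compare the base habitat hypotheses
#'
#' Corridors (dForest + dStream), Human Footprint (dAg + dRoad), and Global
#' (all four), each with the tier-1 functional forms plus step length,
#' ranked by AICc.
#'
#' @param design step design data.frame.
#' @param forms named vector of forms from [tier1_select_forms()].
#' @return list with `best` (term list), `fits`, and a comparison `table`
#'   (model, k, AICc, dAICc, w, LL).
#' @export
tier2_select_base <- function(design, forms) {
  hyp <- list(Corridors = c("dForest", "dStream"),
              HumanFootprint = c("dAg", "dRoad"),
              Global = c("dForest", "dStream", "dAg", "dRoad"))
  fits <- lapply(hyp, function(vars)
    fit_spec(design, lapply(vars, function(v)
      ssf_term(v, forms[[v]], "distance"))))
  tab <- selection_table(names(hyp), fits)
  best <- names(hyp)[which.min(vapply(fits, function(f) f$aicc, 0))]
  list(best = fits[[best]]$terms, best_name = best, fits = fits,
       table = tab)
}

selection_table <- function(labels, fits) {
  a <- vapply(fits, function(f) f$aicc, 0)
  tab <- data.frame(model = labels,
                    k = vapply(fits, function(f) f$k, 0),
                    AICc = a, dAICc = a - min(a),
                    w = akaike_weights(a),
                    LL = vapply(fits, function(f) f$loglik, 0))
  tab[order(tab$AICc), ]
}

#' Tier 3: dissimilarity grain and form selection
#'
#' Starting from the tier-2 base model, selects the best grain and
#' functional form for the pooled dissimilarity D_ALL (added to the base)
#' and then for the movement-specific dissimilarity D_IND (added to base +
#' D_ALL), each by AICc over grains x forms.  If the Pearson correlation
#' between the chosen D_ALL and D_IND model columns exceeds `r_max` the
#' D_IND choice is demoted to the next-best candidate (to a depth of
#' three); if every candidate within that depth is correlated, D_IND is
#' omitted and flagged.  Returns the three nested fits with their AICc
#' table, Akaike weights, and main-effect VIFs of the largest model.
#'
#' @param design step design data.frame with `D_ALL_<grain>` and
#'   `D_IND_<grain>` columns.
#' @param base_terms term list of the tier-2 winner.
#' @param grains grain radii to consider, m.
#' @param forms functional forms to consider for dissimilarity terms.
#' @param r_max correlation ceiling (the "r > 0.70" rule).
#' @param fallback_depth how many ranked D_IND candidates may be tried.
#' @return list with `fits` (base, base_all, base_all_ind), `table`,
#'   `weights`, `d_all`/`d_ind` chosen terms, `vif`, and flags.
#' @export
tier3_select_dissimilarity <- function(design, base_terms,
                                       grains = c(175, 250, 350, 500),
                                       forms = c("linear", "ln"),
                                       r_max = 0.70, fallback_depth = 3) {
  cand <- expand.grid(grain = grains, form = forms,
                      stringsAsFactors = FALSE)
  fit_cand <- function(prefix, extra_terms) {
    lapply(seq_len(nrow(cand)), function(i) {
      v <- paste0(prefix, "_", cand$grain[i])
      if (!v %in% names(design)) return(NULL)
      tryCatch(fit_spec(design, c(extra_terms, list(
        ssf_term(v, cand$form[i], "dissimilarity")))),
        error = function(e) NULL)
    })
  }
  base_fit <- fit_spec(design, base_terms)

  all_fits <- fit_cand("D_ALL", base_terms)
  ok <- !vapply(all_fits, is.null, TRUE)
  if (!any(ok)) stop("no D_ALL candidate could be fitted")
  ia <- which(ok)[which.min(vapply(all_fits[ok], function(f) f$aicc, 0))]
  fit_all <- all_fits[[ia]]
  term_all <- fit_all$terms[[length(fit_all$terms)]]

  ind_fits <- fit_cand("D_IND", fit_all$terms)
  ok <- !vapply(ind_fits, is.null, TRUE)
  ranked <- which(ok)[order(vapply(ind_fits[ok], function(f) f$aicc, 0))]
  col_of <- function(term) term_columns(design[[term$var]], term)[[1]]
  z_all <- col_of(term_all)
  fit_ind <- NULL
  demoted <- 0
  for (i in head(ranked, fallback_depth)) {
    term_ind <- ind_fits[[i]]$terms[[length(ind_fits[[i]]$terms)]]
    z_ind <- col_of(term_ind)
    use <- is.finite(z_all) & is.finite(z_ind)
    r <- suppressWarnings(cor(z_all[use], z_ind[use]))
    if (is.na(r) || r <= r_max) {
      fit_ind <- ind_fits[[i]]
      break
    }
    demoted <- demoted + 1
  }
  fits <- list(base = base_fit, base_all = fit_all)
  labels <- c("Base", paste0("Base + ", spec_label(term_all)))
  if (!is.null(fit_ind)) {
    fits$base_all_ind <- fit_ind
    labels <- c(labels, paste0("Base + ", spec_label(term_all), " + ",
                               spec_label(fit_ind$terms[[
                                 length(fit_ind$terms)]])))
  }
  tab <- selection_table(labels, fits)
  w <- setNames(akaike_weights(vapply(fits, function(f) f$aicc, 0)),
                names(fits))
  final <- fits[[length(fits)]]
  Xmain <- ssf_model_matrix(design, final$terms, step_length = FALSE)
  Xmain <- Xmain[is.finite(rowSums(Xmain)), , drop = FALSE]
  v <- tryCatch(vif(Xmain), error = function(e) NULL)
  list(fits = fits, table = tab, weights = w,
       d_all = term_all,
       d_ind = if (!is.null(fit_ind))
         fit_ind$terms[[length(fit_ind$terms)]] else NULL,
       vif = v, demoted = demoted, d_ind_omitted = is.null(fit_ind))
}

spec_label <- function(term) {
  switch(term$form,
         linear = term$var,
         quadratic = paste0(term$var, " + ", term$var, "^2"),
         ln = paste0("ln(", term$var, ")"))
}

#' Model-averaged log relative selection strength
#'
#' For a grid of values `v` of a focus covariate, each model's
#' `ln RSS = sum_focus-terms beta (f(v) - f(v_ref))` relative to a
#' reference location, with all other covariates held at their design means
#' (where they contribute zero); models lacking the focus covariate
#' contribute zero.  The curve is the Akaike-weight-averaged prediction and
#' its 95% band comes from parametric resampling of each model's
#' coefficients from the fitted variance-covariance.
#'
#' @param fits named list of `clr_fit`s (with `terms`).
#' @param weights matching Akaike weights.
#' @param design step design data.frame (for the reference mean).
#' @param focus_var design column name of the focus covariate.
#' @param v_grid grid of focus-covariate values (default 100 points over
#'   the design range).
#' @param v_ref reference value (default: design mean of the covariate).
#' @param nboot resampling draws for the confidence band.
#' @param seed RNG seed for the band.
#' @return data.frame with `v`, `lnRSS`, `lower`, `upper`.
#' @export
model_average_rss <- function(fits, weights, design, focus_var,
                              v_grid = NULL, v_ref = NULL, nboot = 2000,
                              seed = 1L) {
  z <- design[[focus_var]]
  if (is.null(v_ref)) v_ref <- mean(z[is.finite(z)])
  if (is.null(v_grid))
    v_grid <- seq(min(z[is.finite(z)]), max(z[is.finite(z)]),
                  length.out = 100)
  has_focus <- vapply(fits, function(f)
    any(vapply(f$terms, function(t) t$var == focus_var, TRUE)), TRUE)
  if (!any(has_focus)) stop("focus covariate absent from every model")

  # per-model f(v) - f(v_ref) design (columns of the focus term only)
  focus_delta <- function(fit, v) {
    i <- which(vapply(fit$terms, function(t) t$var == focus_var, TRUE))[1]
    term <- fit$terms[[i]]
    fv <- do.call(cbind, term_columns(v, term))
    fr <- do.call(cbind, term_columns(v_ref, term))
    sweep(fv, 2, fr)  # columns named as in the model matrix
  }
  curve_for <- function(fit, beta) {
    if (is.null(fit)) return(rep(0, length(v_grid)))
    D <- focus_delta(fit, v_grid)
    drop(D %*% beta[colnames(D)])
  }
  point <- rep(0, length(v_grid))
  for (m in seq_along(fits))
    if (has_focus[m])
      point <- point + weights[m] * curve_for(fits[[m]], fits[[m]]$beta)

  draws <- matrix(0, nboot, length(v_grid))
  withr_seed(seed, {
    for (m in seq_along(fits)) {
      if (!has_focus[m]) next
      fit <- fits[[m]]
      bs <- MASS::mvrnorm(nboot, fit$beta[fit$vcov_names], fit$vcov)
      colnames(bs) <- fit$vcov_names
      D <- focus_delta(fit, v_grid)
      draws <- draws + weights[m] * tcrossprod(bs[, colnames(D),
                                                  drop = FALSE], D)
    }
  })
  band <- apply(draws, 2, quantile, c(0.025, 0.975))
  data.frame(v = v_grid, lnRSS = point, lower = band[1, ],
             upper = band[2, ])
}
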