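#' Specify a regression design for the cecal-length allometry
#'
#' A design always regresses \code{log_cecum} on \code{log_mass}; factors
#' among diet, clade, and flight enter as additive intercept offsets
#' (treatment coding against a reference level), or — for exactly one
#' factor — interactively, giving each level its own slope. Interactions
#' with more than one factor are refused: cell sizes in this kind of
#' comparative sample are too small to estimate them.
#'
#' @param factors Character subset of \code{c("diet", "clade", "flight")}.
#' @param interaction Logical; different slopes per factor level (allowed
#'   only with exactly one factor).
#' @param reference_levels Named character vector giving the reference level
#'   for any included factor, e.g. \code{c(clade = "Inopinaves", diet =
#'   "carnivore-vertebrates")}; unnamed factors keep the first vocabulary
#'   level.
#' @param response,covariate Column names; defaults fit the study design.
#' @return An object of class \code{"design_spec"}.
#' @export
design_spec <- function(factors = character(), interaction = FALSE,
                        reference_levels = character(),
                        response = "log_cecum", covariate = "log_mass") {
  factors <- as.character(factors)
  stopifnot(all(factors %in% c("diet", "clade", "flight")))
  if (interaction && length(factors) != 1L) {
    stop("interaction designs require exactly one factor")
  }
  bad_ref <- setdiff(names(reference_levels), factors)
  if (length(bad_ref)) {
    stop("reference level given for factor(s) not in design: ",
         paste(bad_ref, collapse = ", "))
  }
  structure(list(response = response, covariate = covariate,
                 factors = factors, interaction = interaction,
                 reference_levels = reference_levels),
            class = "design_spec")
}

#' @export
print.design_spec <- function(x, ...) {
  lab <- design_label(x)
  cat("Design:", x$response, "~", x$covariate,
      if (length(x$factors)) paste0("(", lab, ")") else "(simple)", "\n")
  invisible(x)
}

design_label <- function(spec) {
  if (!length(spec$factors)) return("simple")
  paste0(if (spec$interaction) "interaction: " else "additive: ",
         paste(spec$factors, collapse = " + "))
}

#' Build the treatment-coded design matrix for a specification
#'
#' Treatment (dummy) coding with the specified reference levels: intercept,
#' the log-mass slope, then L-1 intercept offsets per included factor, and
#' for an interaction design additionally L-1 slope-modifier columns. Every
#' factor level used must actually occur in the data.
#'
#' @param traits An aligned \code{trait_table}.
#' @param spec A \code{\link{design_spec}}.
#' @return List with \code{X} (model matrix), \code{y} (response vector),
#'   \code{labels} (column names), \code{spec}.
#' @export
build_design <- function(traits, spec) {
  stopifnot(inherits(spec, "design_spec"))
  df <- as.data.frame(traits)
  for (f in spec$factors) {
    present <- unique(as.character(df[[f]]))
    absent <- setdiff(levels(df[[f]]), present)
    if (length(absent)) {
      stop("factor '", f, "' has level(s) absent from data: ",
           paste(absent, collapse = ", "))
    }
    ref <- if (f %in% names(spec$reference_levels)) {
      spec$reference_levels[[f]]
    } else {
      levels(df[[f]])[1]
    }
    if (!ref %in% present) stop("reference level '", ref, "' absent from data")
    df[[f]] <- stats::relevel(df[[f]], ref = ref)
  }
  rhs <- if (!length(spec$factors)) {
    spec$covariate
  } else if (spec$interaction) {
    paste(spec$covariate, "*", spec$factors)
  } else {
    paste(c(spec$covariate, spec$factors), collapse = " + ")
  }
  fml <- stats::as.formula(paste("~", rhs))
  X <- stats::model.matrix(fml, data = df)
  list(X = X, y = df[[spec$response]], labels = colnames(X), spec = spec)
}

# Correlation/covariance structure used as GLS weights for one evolution
# model. "independent" is ordinary least squares (identity); the lambda and
# OU structures are derived from the Brownian matrix C.
model_weights <- function(C, model) {
  n <- nrow(C)
  switch(model$kind,
    independent = diag(n),
    brownian = C,
    lambda = transform_covariance(C, model),
    ou = transform_covariance(C, model)
  )
}

# Core GLS solve for fixed weights V: returns estimates, exact ML normal
# log-likelihood (sigma2 profiled with divisor n), and SEs based on the
# df-adjusted residual variance (divisor n - p), the usual basis for
# t-tests on coefficients.
gls_core <- function(y, X, V) {
  n <- length(y)
  p <- ncol(X)
  L <- tryCatch(chol(V), error = function(e) NULL)
  if (is.null(L)) stop("weight matrix is not positive definite")
  yt <- backsolve(L, y, transpose = TRUE)
  Xt <- backsolve(L, X, transpose = TRUE)
  qrX <- qr(Xt)
  if (qrX$rank < p) {
    drop_cols <- colnames(X)[qrX$pivot[(qrX$rank + 1):p]]
    stop("design matrix is rank deficient; collinear column(s): ",
         paste(drop_cols, collapse = ", "))
  }
  XtVX <- crossprod(Xt)
  beta <- solve(XtVX, crossprod(Xt, yt))
  r <- yt - Xt %*% beta
  rss <- sum(r^2)
  sigma2_ml <- rss / n
  logdet <- 2 * sum(log(diag(L)))
  loglik <- -0.5 * (n * log(2 * pi) + n * log(sigma2_ml) + logdet + n)
  XtX_inv <- chol2inv(chol(XtVX))
  sigma2_resid <- rss / (n - p)
  se <- sqrt(sigma2_resid * diag(XtX_inv))
  fitted <- as.numeric(X %*% beta)
  list(beta = stats::setNames(as.numeric(beta), colnames(X)),
       se = stats::setNames(se, colnames(X)),
       loglik = loglik, sigma2_ml = sigma2_ml, sigma2_resid = sigma2_resid,
       fitted = fitted, residuals = y - fitted, n = n, p = p)
}

#' Generalized least squares under a phylogenetic evolution model
#'
#' Fits \code{y = X beta + e} with \code{e ~ N(0, sigma2 V)}, where \code{V}
#' is the weight structure implied by the evolution model: identity
#' (independent residuals, i.e. OLS), the Brownian covariance \code{C},
#' its lambda transform, or the Ornstein-Uhlenbeck correlation
#' \code{exp(-alpha d)} on patristic distances. The residual scale is
#' profiled by maximum likelihood (divisor n), so log-likelihoods and AICs
#' are comparable across designs; coefficient standard errors use the
#' df-adjusted variance (divisor n - p) as in standard GLS t-tests. For an
#' OU model without a fixed \code{alpha}, alpha is estimated by profile
#' likelihood over a log-spaced grid followed by bounded refinement.
#'
#' @param y Response vector.
#' @param X Design matrix (full column rank).
#' @param C Brownian phylogenetic covariance for the same taxa, in the same
#'   order.
#' @param model An \code{\link{evo_model}}; \code{evo_model("ou")} is not
#'   valid input — pass \code{model = "ou"} (character) or an
#'   \code{evo_model} with fixed \code{alpha}.
#' @return An object of class \code{"gls_fit"}.
#' @export
gls_fit <- function(y, X, C, model) {
  if (is.character(model)) {
    model <- if (model == "ou") list(kind = "ou_profile") else evo_model(model)
  }
  stopifnot(length(y) == nrow(X), nrow(C) == length(y))
  alpha_estimated <- FALSE
  if (identical(model$kind, "ou_profile")) {
    alpha_estimated <- TRUE
    D <- outer(diag(C), diag(C), "+") - 2 * C
    depth <- max(diag(C))
    lower <- 1e-6
    upper <- 50 / depth * 10
    obj <- function(log_alpha) {
      gls_core(y, X, exp(-exp(log_alpha) * D))$loglik
    }
    grid <- seq(log(lower), log(upper), length.out = 30)
    ll_grid <- vapply(grid, obj, numeric(1))
    i <- which.max(ll_grid)
    lo <- grid[max(1, i - 1)]
    hi <- grid[min(length(grid), i + 1)]
    opt <- stats::optimize(obj, interval = c(lo, hi), maximum = TRUE,
                           tol = 1e-6)
    alpha_hat <- if (opt$objective >= ll_grid[i]) exp(opt$maximum) else exp(grid[i])
    model <- evo_model("ou", alpha = alpha_hat)
  }
  V <- model_weights(C, model)
  core <- gls_core(y, X, V)
  k <- core$p + 1L + as.integer(alpha_estimated)
  structure(c(core, list(
    k = k,
    aic = -2 * core$loglik + 2 * k,
    df_resid = core$n - core$p,
    model = model,
    alpha_estimated = alpha_estimated
  )), class = "gls_fit")
}

#' @export
print.gls_fit <- function(x, ...) {
  cat("Phylogenetic GLS fit —", x$model$kind)
  if (x$model$kind == "ou") {
    cat(sprintf(" (alpha = %.4f%s)", x$model$alpha,
                if (x$alpha_estimated) ", estimated" else ""))
  }
  cat("\n")
  tab <- coef_table(x)
  print(format(tab, digits = 4))
  cat(sprintf("logLik = %.3f, k = %d, AIC = %.2f, residual df = %d\n",
              x$loglik, x$k, x$aic, x$df_resid))
  invisible(x)
}

#' Coefficient table with two-sided t-tests
#'
#' @param fit A \code{"gls_fit"}.
#' @param hypothesized Null value tested for every coefficient (default 0).
#' @return Data frame with Value, SE, t, and p-value columns.
#' @export
coef_table <- function(fit, hypothesized = 0) {
  t <- (fit$beta - hypothesized) / fit$se
  p <- 2 * stats::pt(-abs(t), df = fit$df_resid)
  data.frame(coefficient = names(fit$beta), value = unname(fit$beta),
             se = unname(fit$se), t = unname(t), p_value = unname(p))
}

#' Test one coefficient against a hypothesized value
#'
#' Two-sided t-test with \code{n - p} degrees of freedom, e.g. the isometry
#' test of the common allometric slope against 1/3.
#'
#' @param fit A \code{"gls_fit"}.
#' @param coefficient Coefficient label (a column of the design matrix).
#' @param hypothesized Null value (default 0).
#' @return List with \code{t}, \code{df}, \code{p}, \code{estimate},
#'   \code{se}.
#' @export
coef_test <- function(fit, coefficient, hypothesized = 0) {
  if (!coefficient %in% names(fit$beta)) {
    stop("no coefficient named '", coefficient, "'; available: ",
         paste(names(fit$beta), collapse = ", "))
  }
  est <- fit$beta[[coefficient]]
  se <- fit$se[[coefficient]]
  t <- (est - hypothesized) / se
  list(t = t, df = fit$df_resid,
       p = 2 * stats::pt(-abs(t), df = fit$df_resid),
       estimate = est, se = se, hypothesized = hypothesized)
}

#' Fit a design specification by phylogenetic GLS
#'
#' High-level entry: builds the design matrix from an aligned trait table,
#' derives the Brownian covariance from the tree, and fits under the
#' requested evolution model (\code{"independent"}, \code{"brownian"},
#' \code{"ou"} with alpha estimated, or an \code{\link{evo_model}} with
#' fixed parameters).
#'
#' @param traits Aligned \code{trait_table} (same taxa and order as
#'   \code{tree}; see \code{\link{align_to_tree}}).
#' @param tree A \code{"phylo"} with branch lengths.
#' @param spec A \code{\link{design_spec}}.
#' @param model Model name or \code{evo_model}.
#' @return A \code{"gls_fit"} carrying the design spec as
#'   attribute-like element \code{spec}.
#' @export
pgls_fit <- function(traits, tree, spec, model = "brownian") {
  stopifnot(identical(canonical_name(traits$species),
                      canonical_name(tree$tip.label)))
  d <- build_design(traits, spec)
  C <- phylo_vcv(tree)
  fit <- gls_fit(d$y, d$X, C, model)
  fit$spec <- spec
  fit
}

#' Refit with different factor reference levels
#'
#' Treatment-coded output contrasts every level against the reference; a
#' refit under new reference levels re-parameterizes the same model space,
#' so fitted values, log-likelihood and AIC are unchanged while the
#' coefficients become contrasts against the new references.
#'
#' @param traits,tree,spec,model As in \code{\link{pgls_fit}}.
#' @param new_reference_levels Named character vector of new references.
#' @return A \code{"gls_fit"}.
#' @export
relevel_fit <- function(traits, tree, spec, new_reference_levels,
                        model = "brownian") {
  spec2 <- design_spec(factors = spec$factors,
                       interaction = spec$interaction,
                       reference_levels = new_reference_levels,
                       response = spec$response, covariate = spec$covariate)
  pgls_fit(traits, tree, spec2, model)
}

#' The study's ladder of candidate designs
#'
#' Simple allometry; the three single-factor additive designs; clade + diet;
#' clade + diet + flight; and the three single-factor interaction designs —
#' nine designs, each fitted under three evolution models by
#' \code{\link{fit_ladder}}.
#'
#' @param reference_levels Named character vector applied to every design
#'   that includes the corresponding factor.
#' @return List of \code{\link{design_spec}} objects.
#' @export
study_designs <- function(reference_levels = c(
    clade = "Inopinaves", diet = "carnivore-vertebrates",
    flight = "strong flyer")) {
  pick <- function(f) reference_levels[names(reference_levels) %in% f]
  list(
    design_spec(),
    design_spec("clade", reference_levels = pick("clade")),
    design_spec("diet", reference_levels = pick("diet")),
    design_spec("flight", reference_levels = pick("flight")),
    design_spec(c("clade", "diet"), reference_levels = pick(c("clade", "diet"))),
    design_spec(c("clade", "diet", "flight"),
                reference_levels = pick(c("clade", "diet", "flight"))),
    design_spec("clade", interaction = TRUE, reference_levels = pick("clade")),
    design_spec("diet", interaction = TRUE, reference_levels = pick("diet")),
    design_spec("flight", interaction = TRUE, reference_levels = pick("flight"))
  )
}

#' Fit every design under every evolution model and rank by AIC
#'
#' Each design is fitted under independent (OLS), Brownian, and OU
#' (alpha estimated) weighting; AIC differences are computed from the
#' unrounded AICs, and models at least 3 AIC units above the best —
#' equivalent to a p-value of about 0.051 — are flagged as rejected.
#' Per-fit failures are caught and reported as missing rows rather than
#' aborting the ladder.
#'
#' @param traits Aligned \code{trait_table}.
#' @param tree Matching \code{"phylo"}.
#' @param specs List of \code{\link{design_spec}}s (default
#'   \code{\link{study_designs}()}).
#' @param models Character vector of evolution models.
#' @param delta_aic_reject Rejection threshold on delta AIC (default 3).
#' @return An object of class \code{"model_ladder"}: \code{table} (one row
#'   per design x model with AIC, delta AIC, fitted alpha, flags) and
#'   \code{fits} (the \code{gls_fit} objects, NULL where a fit failed).
#' @export
fit_ladder <- function(traits, tree, specs = study_designs(),
                       models = c("independent", "brownian", "ou"),
                       delta_aic_reject = 3) {
  rows <- list()
  fits <- list()
  idx <- 0L
  for (spec in specs) {
    for (m in models) {
      idx <- idx + 1L
      fit <- tryCatch(pgls_fit(traits, tree, spec, model = m),
                      error = function(e) {
                        message("fit_ladder: ", design_label(spec), " / ", m,
                                " failed: ", conditionMessage(e))
                        NULL
                      })
      fits[[idx]] <- fit
      rows[[idx]] <- data.frame(
        design = design_label(spec), model = m,
        alpha = if (!is.null(fit) && fit$model$kind == "ou")
                  fit$model$alpha else NA_real_,
        k = if (is.null(fit)) NA_integer_ else fit$k,
        loglik = if (is.null(fit)) NA_real_ else fit$loglik,
        aic = if (is.null(fit)) NA_real_ else fit$aic,
        stringsAsFactors = FALSE
      )
    }
  }
  tab <- do.call(rbind, rows)
  tab$delta_aic <- tab$aic - min(tab$aic, na.rm = TRUE)
  tab$best <- !is.na(tab$delta_aic) & tab$delta_aic == 0
  tab$rejected <- !is.na(tab$delta_aic) & tab$delta_aic >= delta_aic_reject
  structure(list(table = tab, fits = fits, specs = specs,
                 delta_aic_reject = delta_aic_reject),
            class = "model_ladder")
}

#' @export
print.model_ladder <- function(x, ...) {
  tab <- x$table
  tab$aic <- round(tab$aic, 1)
  tab$delta_aic <- round(tab$delta_aic, 1)
  tab$loglik <- round(tab$loglik, 2)
  tab$alpha <- signif(tab$alpha, 3)
  tab$flag <- ifelse(tab$best, "*", ifelse(tab$rejected, "rejected", ""))
  print(tab[, c("design", "model", "alpha", "k", "aic", "delta_aic", "flag")],
        row.names = FALSE)
  invisible(x)
}

#' Best fit of a ladder
#'
#' @param ladder A \code{"model_ladder"}.
#' @return The \code{"gls_fit"} with the lowest AIC.
#' @export
best_fit <- function(ladder) {
  stopifnot(inherits(ladder, "model_ladder"))
  ladder$fits[[which(ladder$table$best)[1]]]
}
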