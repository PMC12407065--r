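#' Normalised centre-of-mass record for one taxon
#'
#' Two size normalisations of the whole-body COM: glenoacetabular (GA)
#' distance, giving coordinates where 0 = acetabulum and 1 = glenoid
#' (anteroposterior and dorsoventral components normalised by the respective
#' GA distances), and total body mass to the power of one third
#' (m kg^(-1/3)). Taxa with degenerate dorsoventral GA spacing get `NA` for
#' the DV GA-normalised coordinate.
#'
#' @param body a `"body_mass_props"`.
#' @param manifest the source `skeleton_manifest`.
#' @return one-row data frame: `taxon`, `model_set`, `total_mass`,
#'   `com_ap_ga`, `com_dv_ga`, `com_ap_m13`, `com_dv_m13`, `dv_degenerate`.
#' @export
normalize_com <- function(body, manifest) {
  stopifnot(inherits(body, "body_mass_props"),
            inherits(manifest, "skeleton_manifest"))
  ga <- suppressWarnings(glenoacetabular_distances(manifest))
  if (ga["ap"] <= 0) stop("anteroposterior glenoacetabular distance is zero",
                          call. = FALSE)
  degen <- attr(ga, "dv_degenerate")
  m13 <- body$total_mass^(1 / 3)
  data.frame(taxon = body$taxon, model_set = body$model_set_name,
             total_mass = body$total_mass,
             com_ap_ga = body$com[1L] / ga["ap"],
             com_dv_ga = if (degen) NA_real_ else body$com[3L] / ga["dv"],
             com_ap_m13 = body$com[1L] / m13,
             com_dv_m13 = body$com[3L] / m13,
             dv_degenerate = degen, row.names = NULL)
}

#' Stylopodial (limb-bone circumference) body mass model
#'
#' Log10-linear relation between body mass (kg) and a shaft-circumference
#' predictor: femoral circumference for bipeds, summed humeral + femoral
#' circumference for quadrupeds. The calibrated coefficients (e.g. from the
#' MASSTIMATE package) are not bundled and must be supplied by the user.
#'
#' @param name `"bipedal"` or `"quadrupedal"`.
#' @param slope,intercept coefficients of
#'   `log10(mass_kg) = intercept + slope * log10(circumference_mm)`;
#'   `slope` must be positive.
#' @param mppe mean absolute percentage prediction error (fraction).
#' @return object of class `"stylopodial_model"`.
#' @export
stylopodial_model <- function(name = c("bipedal", "quadrupedal"),
                              slope, intercept, mppe = 0) {
  name <- match.arg(name)
  if (missing(slope) || missing(intercept) ||
      !is.finite(slope) || !is.finite(intercept)) {
    stop("stylopodial coefficients missing: supply slope and intercept from ",
         "your calibration config (they are not bundled)", call. = FALSE)
  }
  if (slope <= 0) stop("stylopodial slope must be positive", call. = FALSE)
  if (!is.finite(mppe) || mppe < 0) stop("mppe must be >= 0", call. = FALSE)
  structure(list(name = name, slope = slope, intercept = intercept,
                 mppe = mppe), class = "stylopodial_model")
}

#' Body mass from limb-bone shaft circumference
#'
#' `mass = 10^(intercept + slope * log10(C))` with symmetric mPPE bounds
#' `mass * (1 -/+ mppe)`.
#'
#' @param circumference_mm shaft circumference predictor (mm); vectorised.
#' @param model a [stylopodial_model()].
#' @return data frame with `circumference_mm`, `mass`, `mass_lower`,
#'   `mass_upper` (kg).
#' @export
stylopodial_mass <- function(circumference_mm, model) {
  stopifnot(inherits(model, "stylopodial_model"))
  if (any(!is.finite(circumference_mm) | circumference_mm <= 0)) {
    stop("circumference must be positive", call. = FALSE)
  }
  mass <- 10^(model$intercept + model$slope * log10(circumference_mm))
  data.frame(circumference_mm = circumference_mm, mass = mass,
             mass_lower = mass * (1 - model$mppe),
             mass_upper = mass * (1 + model$mppe))
}

#' Spearman's rank correlation
#'
#' Pearson correlation of mid-ranks (ties allowed). Used to compare the
#' ranked ordering of body mass or COM estimates between model sets and
#' against external estimates.
#'
#' @param x,y numeric vectors of equal length >= 3.
#' @return rho in \[-1, 1\]; `NA` with a warning if either vector is constant
#'   (rho undefined).
#' @export
spearman_rho <- function(x, y) {
  stopifnot(length(x) == length(y), length(x) >= 3L)
  if (stats::sd(x) == 0 || stats::sd(y) == 0) {
    warning("Spearman's rho undefined for a constant vector", call. = FALSE)
    return(NA_real_)
  }
  stats::cor(x, y, method = "spearman")
}

#' Sample-size corrected Akaike information criterion
#'
#' `AICc = -2 loglik + 2k + 2k(k+1)/(n-k-1)`.
#'
#' @param loglik maximised log-likelihood.
#' @param k number of estimated parameters (including the variance).
#' @param n sample size; must exceed `k + 1`.
#' @return AICc value.
#' @export
aicc <- function(loglik, k, n) {
  stopifnot(is.finite(loglik), k >= 1)
  if (n <= k + 1) stop("AICc undefined for n <= k + 1", call. = FALSE)
  -2 * loglik + 2 * k + 2 * k * (k + 1) / (n - k - 1)
}

#' Allometric regression by OLS or Brownian-motion PGLS
#'
#' Fits `y ~ x` (typically log10-transformed dimensions against log10 body
#' mass) by ordinary least squares or by phylogenetic generalised least
#' squares with residual covariance proportional to shared path lengths under
#' Brownian motion (via [nlme::gls()] with [ape::corBrownian()], ML
#' estimation). An isometric expectation, when supplied, yields an allometry
#' verdict from the 95% confidence interval of the slope: `"positive"` if the
#' CI lies above it, `"negative"` if below, `"isometry-within-CI"` otherwise.
#'
#' For PGLS the (adjusted) R^2 is computed on the generalised scale:
#' `1 - (e' C^-1 e) / (e0' C^-1 e0)` where `e` are residuals from the fit and
#' `e0` residuals from the GLS mean, `C` the Brownian covariance.
#'
#' @param y response vector.
#' @param x predictor vector.
#' @param taxa taxon labels for `y`/`x`; required for PGLS (must match the
#'   tree's tip labels). Defaults to `names(y)`.
#' @param tree an `ape::phylo` time-calibrated tree (PGLS only).
#' @param method `"OLS"` or `"PGLS"`.
#' @param iso_slope optional isometric slope expectation (e.g. 1 for
#'   mass-mass, 1/3 for length-mass).
#' @return object of class `"allometry_fit"`: `slope`, `intercept`,
#'   `slope_ci` (95%), `adj_r2`, `loglik`, `aicc`, `n`, `method`, `verdict`.
#' @export
fit_allometry <- function(y, x, taxa = names(y), tree = NULL,
                          method = c("OLS", "PGLS"), iso_slope = NULL) {
  method <- match.arg(method)
  stopifnot(length(y) == length(x))
  n <- length(y)
  if (n < 3L) stop("need at least 3 observations", call. = FALSE)
  if (stats::sd(x) == 0) stop("singular design: constant predictor", call. = FALSE)

  if (method == "OLS") {
    fit <- stats::lm(y ~ x)
    co <- summary(fit)$coefficients
    slope <- co["x", "Estimate"]; se <- co["x", "Std. Error"]
    intercept <- co["(Intercept)", "Estimate"]
    adj_r2 <- summary(fit)$adj.r.squared
    ll <- as.numeric(stats::logLik(fit))
  } else {
    if (is.null(tree)) stop("PGLS needs a tree", call. = FALSE)
    if (is.null(taxa)) stop("PGLS needs taxon labels (taxa or names(y))",
                            call. = FALSE)
    if (!all(taxa %in% tree$tip.label) || length(taxa) != ape::Ntip(tree)) {
      stop("taxa must match the tree's tip labels one-to-one", call. = FALSE)
    }
    df <- data.frame(y = y, x = x, taxon = taxa)
    fit <- nlme::gls(y ~ x, data = df,
                     correlation = ape::corBrownian(1, tree, form = ~taxon),
                     method = "ML")
    co <- summary(fit)$tTable
    slope <- co["x", "Value"]; se <- co["x", "Std.Error"]
    intercept <- co["(Intercept)", "Value"]
    ll <- as.numeric(stats::logLik(fit))
    # generalised R^2 against the GLS mean
    C <- ape::vcv(tree)[taxa, taxa]
    Ci <- solve(C)
    e <- y - (intercept + slope * x)
    one <- rep(1, n)
    mu <- as.numeric((one %*% Ci %*% y) / (one %*% Ci %*% one))
    e0 <- y - mu
    r2 <- 1 - as.numeric(e %*% Ci %*% e) / as.numeric(e0 %*% Ci %*% e0)
    adj_r2 <- 1 - (1 - r2) * (n - 1) / (n - 2)
  }
  tcrit <- stats::qt(0.975, df = n - 2)
  ci <- c(slope - tcrit * se, slope + tcrit * se)
  verdict <- NA_character_
  if (!is.null(iso_slope)) {
    verdict <- if (ci[1L] > iso_slope) "positive"
               else if (ci[2L] < iso_slope) "negative"
               else "isometry-within-CI"
  }
  structure(list(slope = slope, intercept = intercept, slope_se = se,
                 slope_ci = ci, adj_r2 = adj_r2, loglik = ll,
                 aicc = aicc(ll, k = 3, n = n), n = n, method = method,
                 iso_slope = iso_slope, verdict = verdict),
            class = "allometry_fit")
}

#' @export
print.allometry_fit <- function(x, ...) {
  cat(sprintf("%s allometric fit (n = %d)\n", x$method, x$n),
      sprintf(" slope: %.4g  [%.4g, %.4g]\n", x$slope, x$slope_ci[1L],
              x$slope_ci[2L]),
      sprintf(" intercept: %.4g | adj R^2: %.3f | AICc: %.2f\n",
              x$intercept, x$adj_r2, x$aicc))
  if (!is.na(x$verdict)) {
    cat(sprintf("  allometry vs slope %.4g: %s\n", x$iso_slope, x$verdict))
  }
  invisible(x)
}

#' Maximum-likelihood ancestral states under Brownian motion
#'
#' Estimates trait values at internal nodes (equivalently the GLS
#' reconstruction; the root state equals the GLS mean). Zero-length terminal
#' branches are replaced by a small epsilon with a warning.
#'
#' @param tree an `ape::phylo` rooted tree with branch lengths.
#' @param tip_values named numeric vector covering every tip.
#' @return named numeric vector of states at internal nodes (names are the
#'   `phylo` node numbers, as from [phytools::fastAnc()]).
#' @export
ancestral_states <- function(tree, tip_values) {
  stopifnot(inherits(tree, "phylo"))
  if (is.null(names(tip_values)) ||
      !setequal(names(tip_values), tree$tip.label)) {
    stop("tip_values must be named by the tree's tip labels (complete)",
         call. = FALSE)
  }
  if (any(tree$edge.length < 0)) stop("negative branch lengths", call. = FALSE)
  term <- tree$edge[, 2L] <= ape::Ntip(tree)
  if (any(tree$edge.length[term] == 0)) {
    eps <- 1e-8 * max(ape::node.depth.edgelength(tree))
    tree$edge.length[term & tree$edge.length == 0] <- eps
    warning("zero-length terminal branches replaced by epsilon = ",
            format(eps), call. = FALSE)
  }
  x <- tip_values[tree$tip.label]
  anc <- phytools::fastAnc(tree, x)
  out <- as.numeric(anc)
  names(out) <- names(anc)
  out
}

#' Phylomorphospace coordinates
#'
#' Tip coordinates are the observed trait pair; internal-node coordinates are
#' Brownian-motion ancestral state reconstructions of each trait; edges follow
#' the tree topology. The result can be plotted with its `plot()` method
#' (points joined by tree edges).
#'
#' @param tree an `ape::phylo` rooted tree.
#' @param trait_x,trait_y named numeric vectors covering every tip.
#' @return object of class `"phylomorphospace_coords"`: list with `nodes`
#'   (data frame `node`, `label`, `type`, `x`, `y`) and `edges` (data frame
#'   `parent`, `child` of node numbers).
#' @export
phylomorphospace <- function(tree, trait_x, trait_y) {
  stopifnot(inherits(tree, "phylo"))
  ax <- ancestral_states(tree, trait_x)
  ay <- suppressWarnings(ancestral_states(tree, trait_y))
  ntip <- ape::Ntip(tree)
  nodes <- data.frame(
    node = seq_len(ntip + tree$Nnode),
    label = c(tree$tip.label, names(ax)),
    type = c(rep("tip", ntip), rep("internal", tree$Nnode)),
    x = c(unname(trait_x[tree$tip.label]), unname(ax)),
    y = c(unname(trait_y[tree$tip.label]), unname(ay)),
    stringsAsFactors = FALSE
  )
  edges <- data.frame(parent = tree$edge[, 1L], child = tree$edge[, 2L])
  structure(list(nodes = nodes, edges = edges), class = "phylomorphospace_coords")
}

#' @export
plot.phylomorphospace_coords <- function(x, xlab = "trait x",
                                         ylab = "trait y", ...) {
  nd <- x$nodes
  graphics::plot(nd$x, nd$y, type = "n", xlab = xlab, ylab = ylab, ...)
  graphics::segments(nd$x[x$edges$parent], nd$y[x$edges$parent],
                     nd$x[x$edges$child], nd$y[x$edges$child], col = "grey60")
  tips <- nd$type == "tip"
  graphics::points(nd$x[!tips], nd$y[!tips], pch = 21, bg = "white", cex = 0.7)
  graphics::points(nd$x[tips], nd$y[tips], pch = 19)
  invisible(x)
}
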