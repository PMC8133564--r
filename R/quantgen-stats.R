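# Population-level statistics: variance components and broad-sense
# heritability from a one-way genotype decomposition, genotype x
# concentration ANOVA, trait correlation matrices, and PCA summaries.

#' Broad-sense heritability from variance components
#'
#' `h2 = sigma_g2 / (sigma_g2 + sigma_e2 / r)`, the fraction of variance
#' among genotype means attributable to genetic variance, with `r` the
#' number of experimental replications per genotype.
#'
#' @param sigma_g2 Genetic variance (>= 0).
#' @param sigma_e2 Residual variance (>= 0).
#' @param r Replication count (> 0); fractional means are allowed.
#' @return Heritability in `[0, 1]` (vectorized).
#' @examples
#' heritability(3, 6, 6) # 0.75
#' @export
heritability <- function(sigma_g2, sigma_e2, r) {
  if (any(r <= 0)) abort("heritability: replication count must be positive")
  if (any(sigma_g2 < 0) || any(sigma_e2 < 0)) {
    abort("heritability: variance components must be non-negative")
  }
  ifelse(sigma_g2 + sigma_e2 / r == 0, NA_real_,
         sigma_g2 / (sigma_g2 + sigma_e2 / r))
}

.vc_one <- function(values, genotype, method, r_method) {
  keep <- !is.na(values) & !is.na(genotype)
  values <- values[keep]
  genotype <- factor(genotype[keep])
  if (nlevels(genotype) < 2) abort("variance_components: need at least 2 genotypes")
  if (var(values) == 0) abort("variance_components: zero total variance")
  if (length(values) - nlevels(genotype) < 1) {
    abort("variance_components: need replicate observations within genotypes (no residual df)")
  }
  counts <- table(genotype)
  r_bar <- switch(r_method,
                  mean = mean(counts),
                  harmonic = length(counts) / sum(1 / counts))
  a <- anova(lm(values ~ genotype))
  ms_g <- a$`Mean Sq`[1]
  ms_e <- a$`Mean Sq`[2]
  if (method == "moments") {
    sigma_e2 <- ms_e
    sigma_g2_raw <- (ms_g - ms_e) / r_bar
  } else {
    fit <- lme4::lmer(values ~ (1 | genotype),
                      control = lme4::lmerControl(check.conv.singular = "ignore"))
    vc <- as.data.frame(lme4::VarCorr(fit))
    sigma_g2_raw <- vc$vcov[vc$grp == "genotype"]
    sigma_e2 <- vc$vcov[vc$grp == "Residual"]
  }
  sigma_g2 <- max(sigma_g2_raw, 0)
  tibble(
    sigma_g2 = sigma_g2, sigma_e2 = sigma_e2, r = r_bar,
    h2 = heritability(sigma_g2, sigma_e2, r_bar),
    sigma_g2_raw = sigma_g2_raw, ms_genotype = ms_g, ms_residual = ms_e,
    df_genotype = a$Df[1], df_residual = a$Df[2],
    n_genotypes = nlevels(genotype), method = method
  )
}

#' Variance components and heritability per trait
#'
#' Decomposes each trait into genetic and residual variance from a one-way
#' genotype classification. The default method-of-moments estimator uses the
#' one-way ANOVA expected mean squares: `sigma_e2 = MS_residual` and
#' `sigma_g2 = max(0, (MS_genotype - MS_residual) / r)` with `r` the
#' arithmetic mean replicate count per genotype (harmonic-mean option
#' available); negative moment estimates are truncated at zero (the raw
#' value is kept in `sigma_g2_raw`). A REML backend (random genotype
#' intercept) is available via `method = "reml"`.
#'
#' @param data Tibble with a genotype column and trait columns.
#' @param traits Character vector of trait column names.
#' @param genotype Name of the genotype column (default `"genotype"`).
#' @param method `"moments"` (default) or `"reml"`.
#' @param r_method `"mean"` (default) or `"harmonic"` replicate count.
#' @return Tibble with one row per trait: `trait`, `sigma_g2`, `sigma_e2`,
#'   `r`, `h2`, `sigma_g2_raw`, mean squares, degrees of freedom, `method`.
#' @export
variance_components <- function(data, traits, genotype = "genotype",
                                method = c("moments", "reml"),
                                r_method = c("mean", "harmonic")) {
  method <- match.arg(method)
  r_method <- match.arg(r_method)
  .require_cols(data, c(genotype, traits), "variance_components input")
  map(traits, function(tr) {
    .vc_one(data[[tr]], data[[genotype]], method, r_method) %>%
      mutate(trait = tr, .before = 1)
  }) %>% list_rbind()
}

#' Genotype x concentration ANOVA
#'
#' Fixed-effects two-way ANOVA (genotype, concentration, their interaction,
#' and optionally a block term) by least squares, with Type II sums of
#' squares so unbalanced data are handled symmetrically.
#'
#' @param data Tibble with the response and factor columns.
#' @param trait Response column name.
#' @param genotype,concentration Factor column names.
#' @param block Optional block column name.
#' @return Tidy tibble: `term`, `df`, `sumsq`, `statistic`, `p.value`.
#' @export
anova_gxc <- function(data, trait, genotype = "genotype",
                      concentration = "treatment", block = NULL) {
  .require_cols(data, c(trait, genotype, concentration, block), "anova_gxc input")
  df <- data[!is.na(data[[trait]]), ]
  y <- df[[trait]]
  if (length(y) < 2 || var(y) == 0) abort("anova_gxc: response has zero variance")
  df$..g <- factor(df[[genotype]])
  df$..c <- factor(df[[concentration]])
  if (nlevels(df$..g) < 2 || nlevels(df$..c) < 2) {
    abort("anova_gxc: both factors need at least 2 levels")
  }
  form <- if (is.null(block)) {
    stats::as.formula(sprintf("`%s` ~ ..g * ..c", trait))
  } else {
    df$..b <- factor(df[[block]])
    stats::as.formula(sprintf("`%s` ~ ..b + ..g * ..c", trait))
  }
  fit <- lm(form, data = df)
  if (any(is.na(coef(fit)))) {
    bad <- names(coef(fit))[is.na(coef(fit))]
    abort(sprintf("anova_gxc: aliased model terms: %s",
                  paste(head(bad, 5), collapse = ", ")))
  }
  tab <- car::Anova(fit, type = 2)
  out <- as_tibble(tab, rownames = "term") %>%
    rename(sumsq = "Sum Sq", df = "Df", statistic = "F value", p.value = "Pr(>F)")
  label <- c("..b0" = "(intercept-only)", "..b" = "block", "..g" = "genotype",
             "..c" = "concentration", "..g:..c" = "genotype:concentration")
  out$term <- ifelse(out$term %in% names(label), label[out$term], out$term)
  out %>% filter(.data$term != "(intercept-only)") %>%
    select("term", "df", "sumsq", "statistic", "p.value")
}

#' Pairwise trait correlation matrix
#'
#' Pearson correlations on pairwise-complete observations with p-values from
#' the t transform. Multiplicity adjustment is off by default
#' (Benjamini-Hochberg available). Constant traits yield missing
#' correlations with a flag instead of an error.
#'
#' @param data Tibble of traits.
#' @param traits Character vector of trait columns (>= 2).
#' @param adjust `"none"` (default) or any [stats::p.adjust()] method.
#' @param min_pairs Minimum complete pairs per trait pair (default 3).
#' @return Tibble of unordered pairs: `trait_a`, `trait_b`, `n`, `r`,
#'   `p.value`, `p.adjusted`, `flagged`; class `"trait_cor"` (see
#'   [autoplot.trait_cor()]).
#' @export
correlation_matrix <- function(data, traits, adjust = "none", min_pairs = 3) {
  stopifnot(length(traits) >= 2)
  .require_cols(data, traits, "correlation_matrix input")
  idx <- utils::combn(length(traits), 2)
  rows <- map(seq_len(ncol(idx)), function(k) {
    ta <- traits[idx[1, k]]
    tb <- traits[idx[2, k]]
    x <- data[[ta]]
    y <- data[[tb]]
    cc <- stats::complete.cases(x, y)
    n <- sum(cc)
    if (n < min_pairs || sd(x[cc]) == 0 || sd(y[cc]) == 0) {
      return(tibble(trait_a = ta, trait_b = tb, n = n, r = NA_real_,
                    p.value = NA_real_, flagged = TRUE))
    }
    ct <- cor.test(x[cc], y[cc], method = "pearson")
    tibble(trait_a = ta, trait_b = tb, n = n, r = unname(ct$estimate),
           p.value = ct$p.value, flagged = FALSE)
  }) %>% list_rbind()
  rows$p.adjusted <- p.adjust(rows$p.value, method = adjust)
  class(rows) <- c("trait_cor", class(rows))
  rows
}

#' Principal component summary of a trait table
#'
#' PCA on complete rows (listwise deletion) with unit-variance scaling by
#' default. Variance-explained fractions always sum to 1.
#'
#' @param data Tibble of traits.
#' @param traits Character vector of trait columns (>= 2).
#' @param scale Scale traits to unit variance (default TRUE).
#' @return A `pca_summary` object: `variance` tibble (component,
#'   variance-explained fraction, cumulative), `loadings` tibble, `scores`
#'   tibble, `n` rows used. Methods: [tidy.pca_summary()],
#'   [autoplot.pca_summary()].
#' @export
pca_summary <- function(data, traits, scale = TRUE) {
  stopifnot(length(traits) >= 2)
  .require_cols(data, traits, "pca_summary input")
  x <- data[, traits]
  cc <- stats::complete.cases(x)
  x <- as.matrix(x[cc, ])
  if (nrow(x) < 2) abort("pca_summary: fewer than 2 complete rows")
  keep <- apply(x, 2, sd) > 0
  if (!all(keep)) {
    warn(sprintf("pca_summary: dropping constant trait(s): %s",
                 paste(traits[!keep], collapse = ", ")))
    x <- x[, keep, drop = FALSE]
  }
  p <- prcomp(x, center = TRUE, scale. = scale)
  ve <- p$sdev^2 / sum(p$sdev^2)
  variance <- tibble(component = paste0("PC", seq_along(ve)),
                     prop_variance = ve, cum_variance = cumsum(ve))
  loadings <- as_tibble(p$rotation, rownames = "trait")
  scores <- as_tibble(p$x)
  structure(list(variance = variance, loadings = loadings, scores = scores,
                 n = nrow(x), scaled = scale),
            class = "pca_summary")
}

#' @export
print.pca_summary <- function(x, ...) {
  cat(sprintf("<pca_summary> n = %d rows, %d components\n", x$n, nrow(x$variance)))
  print(head(x$variance, 5))
  invisible(x)
}

#' @rdname pca_summary
#' @param x A `pca_summary`.
#' @param ... Unused.
#' @method tidy pca_summary
#' @export
tidy.pca_summary <- function(x, ...) x$variance

#' @rdname pca_summary
#' @method glance pca_summary
#' @export
glance.pca_summary <- function(x, ...) {
  tibble(n = x$n, n_components = nrow(x$variance),
         pc1_pc2_variance = sum(x$variance$prop_variance[1:min(2, nrow(x$variance))]))
}
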