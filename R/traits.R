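#' Box-Cox transformation with a normality screen
#'
#' Transforms a positive trait with the Box-Cox power family when, and only
#' when, a Shapiro-Wilk screen rejects normality at `screen_alpha`. The
#' exponent `lambda` maximises the profile log-likelihood over a fixed grid
#' (default -2 to 2 in steps of 0.1); the transform is `(x^lambda - 1) /
#' lambda`, or `log(x)` at `lambda = 0`.
#'
#' @param x Positive numeric vector.
#' @param lambda_grid Candidate exponents.
#' @param screen_alpha Shapiro-Wilk significance level below which the
#'   transform is applied (default 0.01).
#' @param force Apply the transform regardless of the screen.
#' @return A list with `values` (transformed or original), `lambda` (`NA`
#'   when not applied) and `applied` (logical).
#' @export
boxcox_transform <- function(x, lambda_grid = seq(-2, 2, by = 0.1),
                             screen_alpha = 0.01, force = FALSE) {
  x <- as.numeric(x)
  if (anyNA(x)) stop("missing values not allowed")
  if (any(x <= 0))
    stop("Box-Cox requires positive values; shift the trait or skip")
  applied <- force
  if (!force) {
    xs <- if (length(x) > 5000) sample(x, 5000) else x
    applied <- length(unique(xs)) > 2 && stats::shapiro.test(xs)$p.value < screen_alpha
  }
  if (!applied)
    return(list(values = x, lambda = NA_real_, applied = FALSE))
  bc <- MASS::boxcox(x ~ 1, data = data.frame(x = x), lambda = lambda_grid,
                     plotit = FALSE)
  lambda <- bc$x[which.max(bc$y)]
  values <- if (abs(lambda) < 1e-12) log(x) else (x^lambda - 1) / lambda
  list(values = values, lambda = lambda, applied = TRUE)
}

#' Allometric height correction of a trait
#'
#' Regresses `log10(trait)` on `log10(height)` by ordinary least squares and
#' returns the residuals as the height-corrected trait. A line whose
#' residual is near zero has the trait value expected for its height;
#' positive residuals mean, e.g., unusually wide vessels for the tree's
#' size. Residuals are orthogonal to `log10(height)` by construction.
#'
#' @param trait,height Paired positive numeric vectors, `n >= 3`.
#' @return An object of class `"height_fit"`: list with `a` (intercept),
#'   `b` (allometric exponent/slope), `residuals` (the corrected trait, log10
#'   scale), `fitted`, and `r_squared`.
#' @examples
#' h <- c(10, 20, 40, 80)
#' fit <- height_correct(10 * h^1.5, h)
#' fit$b          # 1.5
#' fit$residuals  # all ~0
#' @export
height_correct <- function(trait, height) {
  if (length(trait) != length(height)) stop("trait and height must be paired")
  ok <- stats::complete.cases(trait, height)
  if (sum(ok) < 3L) stop("need at least 3 complete pairs")
  if (any(trait[ok] <= 0) || any(height[ok] <= 0))
    stop("log-log correction requires positive trait and height values")
  if (stats::sd(height[ok]) == 0) stop("height has zero variance")
  lt <- log10(trait); lh <- log10(height)
  fit <- stats::lm(lt ~ lh, subset = ok)
  res <- rep(NA_real_, length(trait))
  res[ok] <- stats::residuals(fit)
  fv <- rep(NA_real_, length(trait))
  fv[ok] <- stats::fitted(fit)
  ss_tot <- sum((lt[ok] - mean(lt[ok]))^2)
  r2 <- if (ss_tot > 0) 1 - sum(res[ok]^2) / ss_tot else NA_real_
  structure(list(a = unname(stats::coef(fit)[1]), b = unname(stats::coef(fit)[2]),
                 residuals = res, fitted = fv, r_squared = r2),
            class = "height_fit")
}

#' @export
print.height_fit <- function(x, ...) {
  cat(sprintf("log10(trait) = %.4f + %.4f * log10(height)   (R^2 = %.3f, n = %d)\n",
              x$a, x$b, x$r_squared, sum(!is.na(x$residuals))))
  invisible(x)
}

#' Pairwise Pearson correlations among traits
#'
#' Computes the Pearson correlation and its two-sided p-value (t
#' distribution, n - 2 df) for every pair of trait columns, using pairwise
#' complete cases. Constant traits yield `NA`.
#'
#' @param traits Data frame or matrix of genotype-mean trait values, one
#'   column per trait.
#' @return An object of class `"trait_cor"`: list of matrices `r`, `p`, `n`.
#' @export
correlation_matrix <- function(traits) {
  traits <- as.data.frame(traits)
  traits <- traits[vapply(traits, is.numeric, logical(1))]
  k <- ncol(traits)
  if (k < 2L) stop("need at least two numeric trait columns")
  nm <- names(traits)
  r <- p <- n <- matrix(NA_real_, k, k, dimnames = list(nm, nm))
  diag(r) <- 1; diag(p) <- 0
  for (i in seq_len(k)) {
    diag(n)[i] <- sum(!is.na(traits[[i]]))
    for (j in seq_len(k)[-seq_len(i)]) {
      ok <- stats::complete.cases(traits[[i]], traits[[j]])
      n[i, j] <- n[j, i] <- sum(ok)
      if (sum(ok) >= 3 && stats::sd(traits[[i]][ok]) > 0 &&
          stats::sd(traits[[j]][ok]) > 0) {
        ct <- stats::cor.test(traits[[i]][ok], traits[[j]][ok])
        r[i, j] <- r[j, i] <- unname(ct$estimate)
        p[i, j] <- p[j, i] <- ct$p.value
      }
    }
  }
  structure(list(r = r, p = p, n = n), class = "trait_cor")
}

#' @export
print.trait_cor <- function(x, digits = 2, ...) {
  stars <- ifelse(is.na(x$p), " ",
                  ifelse(x$p <= 0.001, "***",
                         ifelse(x$p <= 0.01, "**",
                                ifelse(x$p <= 0.05, "*", " "))))
  m <- matrix(paste0(format(round(x$r, digits)), stars),
              nrow(x$r), dimnames = dimnames(x$r))
  diag(m) <- "1"
  m[upper.tri(m)] <- ""
  print(m, quote = FALSE)
  cat("significance: * p<=0.05, ** p<=0.01, *** p<=0.001\n")
  invisible(x)
}

#' Genotype and height ANOVA for a trait
#'
#' Fits a linear model with genotype (categorical) and tree height
#' (continuous covariate), optionally their interaction, and returns the
#' sequential (Type I) analysis-of-variance table in the order genotype,
#' height, interaction.
#'
#' @param trait Numeric response.
#' @param line Genotype labels (coerced to factor).
#' @param height Optional tree height covariate; `NULL` for a genotype-only
#'   model (as used for height-corrected traits).
#' @param include_interaction Include the genotype x height interaction.
#' @return The `anova` table of the fitted model (class `"anova"`).
#' @export
genotype_anova <- function(trait, line, height = NULL,
                           include_interaction = TRUE) {
  line <- factor(line)
  if (nlevels(line) < 2L) stop("need at least two genotypes")
  dat <- data.frame(y = trait, line = line)
  if (is.null(height)) {
    fit <- stats::lm(y ~ line, data = dat)
  } else {
    dat$height <- height
    fit <- if (include_interaction)
      stats::lm(y ~ line + height + line:height, data = dat)
    else stats::lm(y ~ line + height, data = dat)
  }
  if (stats::df.residual(fit) < 2L)
    stop("saturated model: no residual degrees of freedom")
  stats::anova(fit)
}

#' Broad-sense heritability as clonal repeatability
#'
#' Estimates broad-sense heritability for clonally replicated genotypes as
#' the intraclass correlation (repeatability) from a one-way genotype
#' ANOVA. The genetic variance is `V_g = (MS_geno - MS_error) / r_bar`,
#' with `r_bar` the expected-mean-squares replicate coefficient
#' `(N - sum(n_i^2) / N) / (k - 1)` (equal to the replicate count under
#' balance); `H^2 = V_g / (V_g + MS_error)`, clipped to `[0, 1]`. The 95%
#' confidence interval comes from F-distribution bounds on the
#' genotype/error variance ratio.
#'
#' @param trait Numeric trait values, one per ramet.
#' @param line Genotype labels.
#' @param conf Confidence level (default 0.95).
#' @return An object of class `"heritability"`: list with `H2`, `ci`
#'   (length-2), `V_g`, `MS_error`, `r_bar`, `F`, `df`.
#' @export
repeatability <- function(trait, line, conf = 0.95) {
  ok <- !is.na(trait) & !is.na(line)
  trait <- trait[ok]; line <- factor(as.character(line[ok]))
  k <- nlevels(line)
  if (k < 2L) stop("need at least two genotypes")
  ni <- as.numeric(table(line))
  N <- sum(ni)
  if (N - k < 1L) stop("no replicated genotype: MS_error undefined")
  av <- stats::anova(stats::lm(trait ~ line))
  MSg <- av$`Mean Sq`[1]; MSe <- av$`Mean Sq`[2]
  df1 <- av$Df[1]; df2 <- av$Df[2]
  r_bar <- (N - sum(ni^2) / N) / (k - 1)
  Vg <- max(0, (MSg - MSe) / r_bar)
  H2 <- if (Vg == 0 && MSe == 0) 0 else Vg / (Vg + MSe)
  if (MSe == 0 && Vg > 0) H2 <- 1
  H2 <- min(max(H2, 0), 1)
  a <- 1 - conf
  if (MSe > 0) {
    Fobs <- MSg / MSe
    FL <- Fobs / stats::qf(1 - a / 2, df1, df2)
    FU <- Fobs / stats::qf(a / 2, df1, df2)
    ci <- c((FL - 1) / (FL + r_bar - 1), (FU - 1) / (FU + r_bar - 1))
    ci <- pmin(pmax(ci, 0), 1)
  } else {
    Fobs <- Inf
    ci <- c(H2, H2)
  }
  structure(list(H2 = H2, ci = ci, V_g = Vg, MS_error = MSe,
                 r_bar = r_bar, F = Fobs, df = c(df1, df2)),
            class = "heritability")
}

#' @export
print.heritability <- function(x, ...) {
  cat(sprintf("H^2 = %.3f  (95%% CI %.3f-%.3f)  V_g = %.4g, MS_error = %.4g, r_bar = %.2f\n",
              x$H2, x$ci[1], x$ci[2], x$V_g, x$MS_error, x$r_bar))
  invisible(x)
}

#' Tukey HSD pairwise comparisons with compact letter display
#'
#' Performs all pairwise comparisons of group means with Tukey's honest
#' significant difference (studentized range, pooled within-group variance)
#' and derives a compact letter display: groups sharing a letter do not
#' differ at the chosen level. Groups with fewer than 2 observations are
#' excluded with a warning.
#'
#' @param values Numeric observations.
#' @param groups Group labels.
#' @param alpha Significance level for the letter display (default 0.05).
#' @return A list with `comparisons` (data frame: pair, difference, adjusted
#'   p) and `letters` (named character vector, one entry per group).
#' @export
tukey_groups <- function(values, groups, alpha = 0.05) {
  ok <- !is.na(values) & !is.na(groups)
  values <- values[ok]; groups <- as.character(groups[ok])
  cnt <- table(groups)
  small <- names(cnt)[cnt < 2]
  if (length(small)) {
    warning("excluding group(s) with < 2 observations: ",
            paste(small, collapse = ", "))
    keep <- !groups %in% small
    values <- values[keep]; groups <- groups[keep]
  }
  g <- factor(groups)
  if (nlevels(g) < 2L) stop("need at least two groups with >= 2 observations")
  fit <- stats::aov(values ~ g)
  tk <- stats::TukeyHSD(fit, conf.level = 1 - alpha)$g
  pairs <- rownames(tk)
  comparisons <- data.frame(pair = pairs, diff = tk[, "diff"],
                            p_adj = tk[, "p adj"], row.names = NULL)
  lev <- levels(g)
  sig <- matrix(FALSE, length(lev), length(lev), dimnames = list(lev, lev))
  for (i in seq_along(pairs)) {
    ab <- strsplit(pairs[i], "-", fixed = TRUE)[[1]]
    sig[ab[1], ab[2]] <- sig[ab[2], ab[1]] <- comparisons$p_adj[i] <= alpha
  }
  list(comparisons = comparisons,
       letters = compact_letters(sig, order(-tapply(values, g, mean))))
}

# insert-and-absorb compact letter display from a logical significance
# matrix (TRUE = the pair differs); `ord` fixes letter assignment order
compact_letters <- function(sig, ord = seq_len(nrow(sig))) {
  lev <- rownames(sig)
  k <- length(lev)
  cols <- list(rep(TRUE, k))  # each column: membership of one letter
  for (i in seq_len(k - 1)) for (j in (i + 1):k) {
    if (!sig[ord[i], ord[j]]) next
    a <- ord[i]; b <- ord[j]
    for (ci in seq_along(cols)) {
      if (cols[[ci]][a] && cols[[ci]][b]) {
        newcol <- cols[[ci]]
        cols[[ci]][a] <- FALSE
        newcol[b] <- FALSE
        cols[[length(cols) + 1L]] <- newcol
      }
    }
    # absorb duplicated/contained columns
    keep <- rep(TRUE, length(cols))
    for (ci in seq_along(cols)) for (cj in seq_along(cols)) {
      if (ci != cj && keep[ci] && keep[cj] &&
          all(cols[[ci]] | !cols[[cj]]) && any(cols[[ci]] != cols[[cj]]))
        keep[cj] <- FALSE
      else if (ci < cj && keep[cj] && identical(cols[[ci]], cols[[cj]]))
        keep[cj] <- FALSE
    }
    cols <- cols[keep]
  }
  out <- vapply(seq_len(k), function(i)
    paste(letters[which(vapply(cols, `[`, logical(1), i))], collapse = ""),
    character(1))
  stats::setNames(out, lev)
}
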