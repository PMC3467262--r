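#' Repeated-measures two-way ANOVA group comparison
#'
#' Mixed-design ANOVA with a between-subjects factor (genotype/group) and a
#' within-subjects factor (stimulus level): the design used to compare
#' response-parameter series between genotypes. The group main effect is
#' tested against the subjects-within-groups stratum; within-subject
#' effects (level, group x level) are reported with and without a
#' Greenhouse-Geisser sphericity correction.
#'
#' @param data long-format data frame with columns `cell` (subject id,
#'   unique across groups), `group`, `level`, `value`
#' @return list: `group` = list(F, df1, df2, p); `level` and
#'   `group_by_level` with uncorrected and GG-corrected p-values;
#'   `gg_epsilon`
#' @export
compare_genotypes <- function(data) {
  stopifnot(all(c("cell", "group", "level", "value") %in% names(data)))
  data$cell <- as.character(data$cell)
  data$group <- as.character(data$group)
  lv <- sort(unique(data$level))
  l <- length(lv)
  # balanced-levels check
  tab <- table(data$cell, data$level)
  bad <- rownames(tab)[rowSums(tab != 1) > 0]
  if (length(bad))
    stop("cells without exactly one value per level: ",
         paste(bad, collapse = ", "))
  cells <- unique(data[, c("cell", "group")])
  if (anyDuplicated(cells$cell))
    stop("cell ids must be unique across groups")
  groups <- unique(cells$group)
  g <- length(groups)
  if (g != 2) stop("exactly two groups required")
  n_i <- table(factor(cells$group, levels = groups))
  if (any(n_i < 2)) stop("need >= 2 cells per group")
  # subject x level matrix, rows ordered by cells
  Y <- matrix(NA_real_, nrow(cells), l,
              dimnames = list(cells$cell, lv))
  Y[cbind(match(data$cell, cells$cell), match(data$level, lv))] <- data$value
  N <- nrow(Y)
  GM <- mean(Y)
  S <- rowMeans(Y)                               # subject means
  G <- stats::setNames(as.vector(tapply(S, cells$group, mean)[groups]),
                       groups)                   # group means
  M <- colMeans(Y)                               # level means
  # between-subjects stratum
  ss_group <- l * sum(as.numeric(n_i) * (G - GM)^2)
  ss_subj <- l * sum((S - G[match(cells$group, groups)])^2)
  df_g <- g - 1; df_s <- sum(n_i - 1)
  F_g <- (ss_group / df_g) / (ss_subj / df_s)
  p_g <- stats::pf(F_g, df_g, df_s, lower.tail = FALSE)
  # within-subjects stratum
  C_ik <- rowsum(Y, cells$group)[groups, , drop = FALSE] /
    as.numeric(n_i)                              # group x level means
  ss_level <- N * sum((M - GM)^2)
  ss_gl <- sum(as.numeric(n_i) *
                 (C_ik - outer(G, rep(1, l)) -
                    outer(rep(1, g), M) + GM)^2)
  resid <- Y - S - C_ik[match(cells$group, groups), , drop = FALSE] +
    G[match(cells$group, groups)]
  ss_err <- sum(resid^2)
  df_l <- l - 1; df_gl <- (g - 1) * (l - 1); df_e <- df_s * (l - 1)
  F_l <- (ss_level / df_l) / (ss_err / df_e)
  F_gl <- (ss_gl / df_gl) / (ss_err / df_e)
  # Greenhouse-Geisser epsilon from the pooled within-group covariance
  Yc <- Y - C_ik[match(cells$group, groups), , drop = FALSE]
  Sig <- crossprod(Yc) / df_s
  Cc <- diag(l) - 1 / l
  V <- Cc %*% Sig %*% Cc
  eps <- sum(diag(V))^2 / (df_l * sum(V * V))
  eps <- min(max(eps, 1 / df_l), 1)
  p_l <- stats::pf(F_l, df_l, df_e, lower.tail = FALSE)
  p_gl <- stats::pf(F_gl, df_gl, df_e, lower.tail = FALSE)
  list(
    group = list(F = F_g, df1 = df_g, df2 = df_s, p = p_g),
    level = list(F = F_l, df1 = df_l, df2 = df_e, p = p_l,
                 p_gg = stats::pf(F_l, df_l * eps, df_e * eps,
                                  lower.tail = FALSE)),
    group_by_level = list(F = F_gl, df1 = df_gl, df2 = df_e, p = p_gl,
                          p_gg = stats::pf(F_gl, df_gl * eps, df_e * eps,
                                           lower.tail = FALSE)),
    gg_epsilon = eps)
}

#' Simulate per-cell series metrics for group comparisons
#'
#' Lightweight metric-level generator (no spike simulation) for calibrating
#' [compare_genotypes()]: each cell contributes a random intercept, each
#' level a shared shift, plus residual noise.
#'
#' @param n_cells cells per group
#' @param group_means named numeric vector, one mean per group
#' @param levels stimulus levels
#' @param level_effect additive shift applied linearly across levels
#'   (default 0)
#' @param cell_cv coefficient of variation of the per-cell random
#'   intercept (default 0.3)
#' @param noise_cv residual CV per observation (default 0.15)
#' @param seed seed
#' @return long data frame (`cell`, `group`, `level`, `value`)
#' @export
simulate_series_metrics <- function(n_cells = 15,
                                    group_means = c(WT = 150, KO = 150),
                                    levels = 1:6, level_effect = 0,
                                    cell_cv = 0.3, noise_cv = 0.15,
                                    seed = 1L) {
  old <- .Random.seed_store()
  set.seed(split_seed(seed, 31))
  out <- list()
  id <- 0L
  for (gname in names(group_means)) {
    mu <- group_means[[gname]]
    for (j in seq_len(n_cells)) {
      id <- id + 1L
      cell_mu <- mu + stats::rnorm(1, 0, cell_cv * mu)
      shift <- level_effect * (seq_along(levels) - 1) / max(1, length(levels) - 1)
      vals <- cell_mu + shift + stats::rnorm(length(levels), 0, noise_cv * mu)
      out[[id]] <- data.frame(cell = sprintf("c%03d", id), group = gname,
                              level = levels, value = vals)
    }
  }
  .Random.seed_restore(old)
  do.call(rbind, out)
}
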