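# Independent oracles, deliberately written with naive loops and textbook
# formulas so they share no code path with the package implementation.

# textbook split-plot sums of squares + Greenhouse-Geisser epsilon, computed
# with explicit loops over cells
oracle_split_plot <- function(d) {
  d$subject <- factor(d$subject)
  d$condition <- factor(d$condition)
  d$region <- factor(d$region)
  a <- nlevels(d$condition); k <- nlevels(d$region)
  n <- nlevels(d$subject) / a
  grand <- mean(d$response)

  ss_cond <- 0
  for (cn in levels(d$condition)) {
    ss_cond <- ss_cond + n * k * (mean(d$response[d$condition == cn]) - grand)^2
  }
  ss_bsub <- 0
  for (s in levels(d$subject)) {
    ss_bsub <- ss_bsub + k * (mean(d$response[d$subject == s]) - grand)^2
  }
  ss_subj_err <- ss_bsub - ss_cond
  ss_reg <- 0
  for (r in levels(d$region)) {
    ss_reg <- ss_reg + n * a * (mean(d$response[d$region == r]) - grand)^2
  }
  ss_int <- 0
  for (cn in levels(d$condition)) for (r in levels(d$region)) {
    m_ab <- mean(d$response[d$condition == cn & d$region == r])
    m_a <- mean(d$response[d$condition == cn])
    m_b <- mean(d$response[d$region == r])
    ss_int <- ss_int + n * (m_ab - m_a - m_b + grand)^2
  }
  ss_tot <- sum((d$response - grand)^2)
  ss_werr <- ss_tot - ss_bsub - ss_reg - ss_int

  df <- list(cond = a - 1, subj = a * (n - 1), reg = k - 1,
             int = (a - 1) * (k - 1), werr = a * (n - 1) * (k - 1))
  F_cond <- (ss_cond / df$cond) / (ss_subj_err / df$subj)
  F_reg <- (ss_reg / df$reg) / (ss_werr / df$werr)
  F_int <- (ss_int / df$int) / (ss_werr / df$werr)

  # pooled within-condition covariance of subject region-vectors, then the
  # classic double-centred epsilon formula
  subjects <- levels(d$subject)
  Y <- matrix(NA_real_, length(subjects), k)
  cond_of <- character(length(subjects))
  for (i in seq_along(subjects)) {
    rows <- d[d$subject == subjects[i], ]
    rows <- rows[order(rows$region), ]
    Y[i, ] <- rows$response
    cond_of[i] <- as.character(rows$condition[1])
  }
  S <- matrix(0, k, k)
  for (cn in unique(cond_of)) {
    Yc <- Y[cond_of == cn, , drop = FALSE]
    Yc <- sweep(Yc, 2, colMeans(Yc))
    S <- S + t(Yc) %*% Yc
  }
  S <- S / (length(subjects) - a)
  # double-centred form of the epsilon
  Sd <- S - matrix(rowMeans(S), k, k) - matrix(colMeans(S), k, k, byrow = TRUE) +
    mean(S)
  eps <- sum(diag(Sd))^2 / ((k - 1) * sum(Sd^2))

  list(
    F_cond = F_cond, F_reg = F_reg, F_int = F_int, epsilon = eps,
    p_cond = pf(F_cond, df$cond, df$subj, lower.tail = FALSE),
    p_reg = pf(F_reg, df$reg * eps, df$werr * eps, lower.tail = FALSE),
    p_int = pf(F_int, df$int * eps, df$werr * eps, lower.tail = FALSE),
    ss = c(cond = ss_cond, subj_err = ss_subj_err, reg = ss_reg,
           int = ss_int, werr = ss_werr, total = ss_tot, bsub = ss_bsub)
  )
}

# direct studentized-range p-values for pairwise condition contrasts on
# subject means
oracle_tukey <- function(d) {
  sm <- aggregate(response ~ subject + condition, data = d, FUN = mean)
  groups <- split(sm$response, sm$condition)
  a <- length(groups); n <- length(groups[[1]])
  mse <- sum(vapply(groups, function(g) sum((g - mean(g))^2), numeric(1))) /
    (a * (n - 1))
  df <- a * (n - 1)
  out <- list()
  nms <- names(groups)
  for (i in seq_len(a - 1)) for (j in (i + 1):a) {
    diff <- mean(groups[[j]]) - mean(groups[[i]])
    q <- abs(diff) / sqrt(mse / n)
    out[[paste0(nms[j], "-", nms[i])]] <- ptukey(q, a, df, lower.tail = FALSE)
  }
  out
}

# run the whole classification pipeline on a phantom and return the
# estimated vs true fractions
phantom_pipeline_fractions <- function(ph, params = morpho_params()) {
  roi <- matrix(TRUE, nrow(ph$labels), ncol(ph$labels))
  maps <- deconvolve(rgb_to_od(ph$image))
  masks <- resolve_classes(
    classify_stain_mask(maps$blue, params, roi),
    classify_stain_mask(maps$red, params, roi),
    detect_adipocytes(ph$image, params, roi),
    roi
  )
  est <- compute_fractions(masks)
  truth <- setNames(ph$true_fractions$fraction * 100, ph$true_fractions$class)
  list(
    est = c(connective = est$connective_pct, myocyte = est$myocyte_pct,
            adipose = est$adipose_pct),
    truth = truth
  )
}

# eight annular-wedge section layout around a centre, with random cut angles
make_wedge_layout <- function(seed = 3, r_inner = 50, r_outer = 100,
                              center = c(0, 0)) {
  set.seed(seed)
  cuts <- sort(runif(8, 0, 360))
  cuts <- c(cuts, cuts[1] + 360)
  secs <- tibble::tibble(
    section_id = paste0("S", 1:8),
    ventricle = c(rep("LV", 6), "RV", "RV"),
    polygon = lapply(1:8, function(i) {
      wedge_polygon(center, r_inner, r_outer, cuts[i], cuts[i + 1])
    })
  )
  slice_layout(secs, center)
}

# random per-section per-layer fractions table matching a layout
make_fractions_table <- function(layout, seed = 4) {
  set.seed(seed)
  fr <- tidyr::expand_grid(
    section_id = layout$sections$section_id,
    layer = c("trabecular", "inner_compact", "outer_compact")
  )
  fr$connective_pct <- runif(nrow(fr), 5, 40)
  fr$adipose_pct <- runif(nrow(fr), 0, 25)
  fr$myocyte_pct <- 100 - fr$connective_pct - fr$adipose_pct
  fr$analyzed_area_px <- sample(1000:5000, nrow(fr))
  fr
}
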