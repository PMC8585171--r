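# shared factorial-design fixtures and long-hand ANOVA oracle

# balanced two-factor dataset with known additive effects, 4 obs per cell
balanced_2x2 <- function(a_eff = 2, b_eff = 0, ab_eff = 0, sd = 0.5,
                         seed = 1) {
  withr::with_seed(seed, {
    d <- tidyr::expand_grid(region = c("SA", "SP"), side = c("left", "right"),
                            rep = 1:4)
    d$y <- 10 + a_eff * (d$region == "SP") + b_eff * (d$side == "right") +
      ab_eff * (d$region == "SP") * (d$side == "right") + rnorm(16, sd = sd)
    d
  })
}

# classical balanced two-way SS decomposition, computed long-hand
hand_anova_2x2 <- function(d) {
  gm <- mean(d$y)
  mA <- tapply(d$y, d$region, mean)
  mB <- tapply(d$y, d$side, mean)
  mAB <- tapply(d$y, interaction(d$region, d$side), mean)
  nA <- 8; nB <- 8; nAB <- 4
  ss_a <- sum(nA * (mA - gm)^2)
  ss_b <- sum(nB * (mB - gm)^2)
  ss_cells <- sum(nAB * (mAB - gm)^2)
  ss_ab <- ss_cells - ss_a - ss_b
  ss_err <- sum((d$y - mAB[interaction(d$region, d$side)])^2)
  list(ss_a = ss_a, ss_b = ss_b, ss_ab = ss_ab, ss_err = ss_err,
       f_a = (ss_a / 1) / (ss_err / 12),
       eta_a = ss_a / (ss_a + ss_err))
}
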