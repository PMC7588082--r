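# Straight-line transcriptions of the model equations, written as
# independent reference implementations for oracle tests.  These are
# deliberately kept free of any package code (no shared helpers beyond
# base R) and follow the update equations literally, one line per
# quantity.

oracle_hgf_binary <- function(u, om2, om3, ka = 1,
                              mu2_0 = 0, sg2_0 = 1, mu3_0 = 1, sg3_0 = 1) {
  n <- length(u)
  muhat1 <- pihat1 <- da1 <- muhat2 <- pihat2 <- mu2 <- pi2 <- numeric(n)
  da2 <- muhat3 <- pihat3 <- mu3 <- pi3 <- numeric(n)
  mu2p <- mu2_0; sg2p <- sg2_0; mu3p <- mu3_0; sg3p <- sg3_0
  for (k in 1:n) {
    muhat2[k] <- mu2p
    muhat3[k] <- mu3p
    pihat2[k] <- 1 / (sg2p + exp(ka * mu3p + om2))
    pihat3[k] <- 1 / (sg3p + exp(om3))
    m1 <- 1 / (1 + exp(-muhat2[k]))
    m1 <- min(max(m1, 1e-8), 1 - 1e-8)
    muhat1[k] <- m1
    pihat1[k] <- 1 / (m1 * (1 - m1))
    da1[k] <- u[k] - m1
    pi2[k] <- pihat2[k] + m1 * (1 - m1)
    mu2[k] <- muhat2[k] + da1[k] / pi2[k]
    da2[k] <- (1 / pi2[k] + (mu2[k] - muhat2[k])^2) * pihat2[k] - 1
    w2 <- exp(ka * mu3p + om2) * pihat2[k]
    pi3[k] <- pihat3[k] + 0.5 * ka^2 * w2 * (w2 + (2 * w2 - 1) * da2[k])
    stopifnot(pi3[k] > 0)
    mu3[k] <- muhat3[k] + 0.5 * (1 / pi3[k]) * ka * w2 * da2[k]
    mu2p <- mu2[k]; sg2p <- 1 / pi2[k]
    mu3p <- mu3[k]; sg3p <- 1 / pi3[k]
  }
  data.frame(muhat1, pihat1, da1, muhat2, pihat2, mu2, pi2, da2,
             muhat3, pihat3, mu3, pi3)
}

oracle_k1 <- function(u, mu_meta, b0 = log(0.1), v0 = 0.5) {
  n <- length(u)
  v <- alpha <- numeric(n)
  vp <- v0; h <- 0; b <- b0
  for (k in 1:n) {
    d <- u[k] - vp
    b <- b + mu_meta * d * h
    a <- min(exp(b), 1)
    vp <- vp + a * d
    h <- h * max(0, 1 - a) + a * d
    v[k] <- vp; alpha[k] <- a
  }
  data.frame(v = v, alpha = alpha)
}

# Combined belief / temperature / follow probability, evaluated literally.
oracle_response <- function(m_gaze, m_card, zeta, variant, mh3c, mh3g,
                            beta, r_g, r_ng, eta) {
  pg <- 1 / (m_gaze * (1 - m_gaze))
  pc <- 1 / (m_card * (1 - m_card))
  wg <- zeta * pg / (zeta * pg + pc)
  wc <- pc / (zeta * pg + pc)
  b <- wg * m_gaze + wc * m_card
  gam <- switch(as.character(variant),
                "1" = beta * exp(-mh3c - mh3g),
                "2" = beta * exp(-mh3g),
                "3" = beta * exp(-mh3c),
                "4" = beta)
  lin <- 1 / (1 + exp(-gam * (r_g * b - r_ng * (1 - b))))
  lg  <- 1 / (1 + exp(-gam * (log(r_g) * b - log(r_ng) * (1 - b))))
  list(b = b, w_gaze = wg, w_card = wc, gamma = gam,
       p = eta * lin + (1 - eta) * lg)
}
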