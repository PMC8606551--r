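# Independent oracles used across the suite.

# Straight-from-publication reimplementation of the ventricular ionic
# model's membrane currents (epicardial variant) in plain R, written
# independently of the compiled kernel; used to cross-check the C++
# transcription at fixed states.
oracle_currents <- function(s, p) {
  R <- 8314.472; Temp <- 310; F <- 96485.3415
  RTF <- R * Temp / F
  Nao <- 140; Cao <- 2; pKNa <- 0.03
  Ko <- p[["K_o"]]
  V <- s[["V"]]; Ki <- s[["K_i"]]; Nai <- s[["Na_i"]]; Cai <- s[["Ca_i"]]
  CaSS <- s[["Ca_ss"]]
  EK <- RTF * log(Ko / Ki)
  ENa <- RTF * log(Nao / Nai)
  EKs <- RTF * log((Ko + pKNa * Nao) / (Ki + pKNa * Nai))
  ECa <- 0.5 * RTF * log(Cao / Cai)
  INa <- p[["ina_scale"]] * 14.838 * s[["m"]]^3 * s[["h"]] * s[["j"]] *
    (V - ENa)
  vf <- 2 * (V - 15) / RTF
  ICaL <- p[["ical_scale"]] * 0.0000398 * s[["d"]] * s[["f"]] *
    s[["f2"]] * s[["fcass"]] * 2 * vf * F *
    (0.25 * CaSS * exp(vf) - Cao) / (exp(vf) - 1)
  Ito <- 0.294 * s[["r"]] * s[["s"]] * (V - EK)
  IKr <- p[["G_Kr"]] * sqrt(Ko / 5.4) * s[["xr1"]] * s[["xr2"]] * (V - EK)
  IKs <- p[["G_Ks"]] * s[["xs"]]^2 * (V - EKs)
  aK1 <- 0.1 / (1 + exp(0.06 * (V - EK - 200)))
  bK1 <- (3 * exp(0.0002 * (V - EK + 100)) + exp(0.1 * (V - EK - 10))) /
    (1 + exp(-0.5 * (V - EK)))
  IK1 <- 5.405 * sqrt(Ko / 5.4) * aK1 / (aK1 + bK1) * (V - EK)
  INaK <- 2.724 * (Ko / (Ko + 1)) * (Nai / (Nai + 40)) /
    (1 + 0.1245 * exp(-0.1 * V / RTF) + 0.0353 * exp(-V / RTF))
  INaCa <- 1000 *
    (exp(0.35 * V / RTF) * Nai^3 * Cao -
       exp(-0.65 * V / RTF) * Nao^3 * Cai * 2.5) /
    ((87.5^3 + Nao^3) * (1.38 + Cao) * (1 + 0.1 * exp(-0.65 * V / RTF)))
  IpCa <- p[["G_pCa"]] * Cai / (Cai + 0.0005)
  IpK <- p[["G_pK"]] * (V - EK) / (1 + exp((25 - V) / 5.98))
  IbNa <- 0.00029 * (V - ENa)
  IbCa <- 0.000592 * (V - ECa)
  IKatp <- p[["g_katp"]] * p[["f_atp"]] * (Ko / 5.4)^0.24 * (V - EK)
  list(I_Na = INa, I_CaL = ICaL, I_NaCa = INaCa, I_pCa = IpCa,
       I_bCa = IbCa, I_Katp = IKatp, E_K = EK, E_Na = ENa, E_Ks = EKs,
       E_Ca = ECa,
       I_total = INa + ICaL + Ito + IKr + IKs + IK1 + INaK + INaCa +
         IpCa + IpK + IbNa + IbCa + IKatp)
}

# AUC as the probability a positive outranks a negative (pair counting)
pair_count_auc <- function(scores, labels) {
  sp <- scores[labels == 1]; sn <- scores[labels == 0]
  mean(outer(sp, sn, ">") + 0.5 * outer(sp, sn, "=="))
}

# brute-force confusion-based metrics at threshold 0.5
brute_metrics <- function(scores, labels) {
  pred <- as.integer(scores >= 0.5)
  tp <- sum(pred & labels); fp <- sum(pred & !labels)
  fn <- sum(!pred & labels); tn <- sum(!pred & !labels)
  c(accuracy = (tp + tn) / length(labels),
    precision = if (tp + fp > 0) tp / (tp + fp) else NA_real_,
    sensitivity = if (tp + fn > 0) tp / (tp + fn) else NA_real_)
}

# small slab with a centred layered ischemic disc, segments and fibers
small_ischemic_slab <- function(nx = 40, ny = 40, radius = 2.5,
                                n_layers = 5, seed = 1) {
  g <- generate_slab(nx, ny, 0.25,
                     ischemia_spec(radius = radius, n_layers = n_layers),
                     seed = seed)
  g <- assign_fibers(assign_aha_segments(g), 60, -60)
  assign_layers(g, n_layers)
}
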