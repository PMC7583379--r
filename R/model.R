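# full ecosystem step: rate assembly, Modified Patankar update, transport -----

# lean light computation used in the hot loop (light_profile wraps this)
light_core <- function(surface_par, grid, phy_att, pom, im, veg,
                       k_bg, k_pom, k_im, k_veg) {
  kd <- k_bg + phy_att + k_pom * pom + k_im * im + k_veg * veg / grid$heights
  tau <- kd * grid$heights
  tau_above <- rev(cumsum(rev(tau)))
  par_bottom <- surface_par * exp(-tau_above)
  par_top <- surface_par * exp(-(tau_above - tau))
  par_mean <- ifelse(tau > 1e-12, (par_top - par_bottom) / tau, par_top)
  list(kd = kd, par_top = par_top, par_mean = par_mean, par_bottom = par_bottom)
}

# one daily (or sub-daily) step of the whole model; `frc` is a list with the
# day's forcing; `cache` holds the static rate-slot plan between steps
model_step <- function(state, frc, grid, pv, dt = 1, cache = new.env()) {
  n <- grid$n_layers
  vol <- grid$volumes
  ben <- pmax(grid$benthic_areas, 1e-9)
  w <- state$water; s <- state$sed
  doy <- doy365(state$day + 1)

  # --- discrete events -------------------------------------------------------
  if (doy <= dt) {          # 1 January: aging juv -> adult, then spawning
    af <- pv[["age_frac"]]; rf <- pv[["fish_repro"]]
    for (x in c("D", "N", "P")) {
      jv <- paste0("FJv", x); ad <- paste0("FAd", x)
      aged <- af * w[jv, ]
      w[ad, ] <- w[ad, ] + aged
      w[jv, ] <- w[jv, ] - aged
      spawn <- rf * w[ad, ]
      w[jv, ] <- w[jv, ] + spawn
      w[ad, ] <- w[ad, ] - spawn
    }
  }
  if (pv[["winter_kill"]] > 0 &&
      doy > pv[["winter_kill_day"]] - dt / 2 &&
      doy <= pv[["winter_kill_day"]] + dt / 2) {
    kf <- pv[["winter_kill"]]
    for (g in c("FJv", "FAd", "FPi")) for (x in c("D", "N", "P")) {
      nm <- paste0(g, x)
      dead_g <- kf * w[nm, ] * vol                  # grams per layer
      s[paste0("POM", x), ] <- s[paste0("POM", x), ] + dead_g / ben
      w[nm, ] <- (1 - kf) * w[nm, ]
    }
  }

  # --- physics ---------------------------------------------------------------
  temp <- water_temperature_step(state$temp, frc$air_temp, frc$swr, grid, dt,
                                 tau0 = pv[["tau_temp"]], z_tau = pv[["z_tau"]],
                                 c_swr = pv[["c_swr"]])
  par0 <- 0.5 * frc$swr
  phy_att <- pv[["k_ext_phy"]] * (w[iW$DiaD, ] + w[iW$CyaD, ] + w[iW$OthD, ])
  lp <- light_core(par0, grid, phy_att, w[iW$POMD, ], w[iW$IM, ], s[iS$VegD, ],
                   pv[["k_bg"]], pv[["k_pom"]], pv[["k_im"]], pv[["k_veg"]])
  tau_shear <- bottom_shear(frc$wind, pv[["fetch"]], grid$depths,
                            z_wave = pv[["z_wave"]])
  cover <- 100 * (1 - exp(-s[iS$VegD, ] / pv[["b_cov"]]))


  # --- rate accumulators (grams per day) -------------------------------------
  first <- is.null(cache$ti)
  if (first) { cache$ti <- integer(512); cache$tj <- integer(512) }
  ntrip_known <- cache$ntrip %||% 512L
  rmat <- matrix(0, ntrip_known, n)
  k_tr <- 0L
  ti <- cache$ti; tj <- cache$tj
  # batched registration: m transfers at once (rows of rm)
  trs <- function(tos, froms, rm) {
    m <- length(tos)
    idx <- k_tr + seq_len(m)
    if (first) {
      ti[idx] <<- PIDX[tos]
      tj[idx] <<- PIDX[froms]
    }
    rmat[idx, ] <<- rm
    k_tr <<- k_tr + m
  }
  loss <- matrix(0, NPOOL, n); src <- matrix(0, NPOOL, n)
  add_loss <- function(pool, r) {
    i <- PIDX[[pool]]; loss[i, ] <<- loss[i, ] + r
  }
  add_src <- function(pool, r) {
    i <- PIDX[[pool]]; src[i, ] <<- src[i, ] + r
  }

  th_min <- temp_factor_abiotic(temp, pv[["theta_min"]])
  th_nit <- temp_factor_abiotic(temp, pv[["theta_nit"]])
  th_den <- temp_factor_abiotic(temp, pv[["theta_den"]])
  th_dif <- temp_factor_abiotic(temp, pv[["theta_dif"]])
  o2 <- w[iW$O2, ]
  y_o2 <- pv[["y_o2_dm"]]

  gross_prod_dm <- numeric(n)
  f_light_grp <- matrix(0, 3, n, dimnames = list(PHYTO_GROUPS, NULL))

  # --- phytoplankton ---------------------------------------------------------
  fd <- pv[["f_diss_mort"]]
  for (g in PHYTO_GROUPS) {
    kk <- PHY_KEYS[[g]]
    dm <- w[kk$iD, ]; gn <- w[kk$iN, ]; gp <- w[kk$iP, ]
    f_i <- lp$par_mean / (lp$par_mean + pv[[kk$h_par]])
    f_t <- temp_factor_biotic(temp, pv[[kk$t_opt]], pv[[kk$t_sig]])
    f_light_grp[g, ] <- f_i
    dms <- pmax.int(dm, 1e-12)
    qn <- pmin.int(pmax.int(gn / dms, pv[["q_min_n"]]), pv[["q_max_n"]])
    qp <- pmin.int(pmax.int(gp / dms, pv[["q_min_p"]]), pv[["q_max_p"]])
    lim <- pmin.int(1 - pv[["q_min_n"]] / qn, 1 - pv[["q_min_p"]] / qp)
    prod <- pv[[kk$mu_max]] * f_t * f_i * lim * dm * vol
    src[kk$pD, ] <- src[kk$pD, ] + prod
    src[PIDX_O2, ] <- src[PIDX_O2, ] + y_o2 * prod
    gross_prod_dm <- gross_prod_dm + prod

    resp <- pv[["k_resp_phy"]] * th_min * dm * vol
    loss[kk$pD, ] <- loss[kk$pD, ] + resp
    loss[PIDX_O2, ] <- loss[PIDX_O2, ] + y_o2 * resp

    mort <- pv[["k_mort_phy"]] * dm * vol
    mort_n <- pv[["k_mort_phy"]] * gn * vol
    mort_p <- pv[["k_mort_phy"]] * gp * vol
    din <- w[iW$NH4, ] + w[iW$NO3, ]
    up_n <- pv[["v_max_n"]] * (pv[["q_max_n"]] - qn) /
      (pv[["q_max_n"]] - pv[["q_min_n"]]) * din / (din + pv[["k_n_upt"]]) * dm * vol
    sh <- nh4_share(w[iW$NH4, ], w[iW$NO3, ], pv[["pref_nh4"]])
    up_p <- pv[[kk$v_max_p]] * (pv[["q_max_p"]] - qp) /
      (pv[["q_max_p"]] - pv[["q_min_p"]]) * w[iW$PO4, ] /
      (w[iW$PO4, ] + pv[[kk$k_p_upt]]) * dm * vol
    trs(c("w.POMD", "w.NH4", "w.POMN", "w.PO4", "w.POMP", kk$wN, kk$wN, kk$wP),
        c(kk$wD, kk$wN, kk$wN, kk$wP, kk$wP, "w.NH4", "w.NO3", "w.PO4"),
        rbind(mort, fd * mort_n, (1 - fd) * mort_n, fd * mort_p,
              (1 - fd) * mort_p, up_n * sh, up_n * (1 - sh), up_p))
  }

  # --- zooplankton -----------------------------------------------------------
  f_t_zoo <- temp_factor_biotic(temp, pv[["zoo_topt"]], pv[["zoo_tsig"]])
  pr_dia <- pv[["pref_zoo_dia"]]; pr_oth <- pv[["pref_zoo_oth"]]
  pr_cya <- pv[["pref_zoo_cya"]]; pr_pom <- pv[["pref_zoo_pom"]]
  f_eff <- pr_dia * w[iW$DiaD, ] + pr_oth * w[iW$OthD, ] +
    pr_cya * w[iW$CyaD, ] + pr_pom * w[iW$POMD, ]
  filt <- pv[["zoo_fmax"]] * f_t_zoo / (1 + f_eff / pv[["zoo_hfood"]]) *
    w[iW$ZooD, ] * vol                                # m^3 swept per day
  ea <- pv[["zoo_assim"]]
  graze_food <- function(pref, idD, idN, idP, wD, wN, wP) {
    g_dm <- filt * pref * w[idD, ]
    fdm <- pmax.int(w[idD, ], 1e-12)
    qn <- w[idN, ] / fdm; qp <- w[idP, ] / fdm
    trs(c("w.ZooD", "w.POMD", "w.ZooN", "w.POMN", "w.ZooP", "w.POMP"),
        c(wD, wD, wN, wN, wP, wP),
        rbind(ea * g_dm, (1 - ea) * g_dm, ea * g_dm * qn, (1 - ea) * g_dm * qn,
              ea * g_dm * qp, (1 - ea) * g_dm * qp))
  }
  graze_food(pr_dia, iW$DiaD, iW$DiaN, iW$DiaP, "w.DiaD", "w.DiaN", "w.DiaP")
  graze_food(pr_oth, iW$OthD, iW$OthN, iW$OthP, "w.OthD", "w.OthN", "w.OthP")
  graze_food(pr_cya, iW$CyaD, iW$CyaN, iW$CyaP, "w.CyaD", "w.CyaN", "w.CyaP")
  g_pom <- filt * pr_pom * w[iW$POMD, ]
  pomds <- pmax.int(w[iW$POMD, ], 1e-12)
  zr <- pv[["zoo_resp"]] * th_min
  zm <- pv[["zoo_mort"]]
  trs(c("w.ZooD", "w.ZooN", "w.ZooP",
        "w.NH4", "w.PO4", "w.POMD", "w.POMN", "w.POMP"),
      c("w.POMD", "w.POMN", "w.POMP",
        "w.ZooN", "w.ZooP", "w.ZooD", "w.ZooN", "w.ZooP"),
      rbind(ea * g_pom, ea * g_pom * w[iW$POMN, ] / pomds,
            ea * g_pom * w[iW$POMP, ] / pomds,
            zr * w[iW$ZooN, ] * vol, zr * w[iW$ZooP, ] * vol,
            zm * w[iW$ZooD, ] * vol, zm * w[iW$ZooN, ] * vol,
            zm * w[iW$ZooP, ] * vol))
  zoo_resp <- zr * w[iW$ZooD, ] * vol
  loss[PIDX[["w.ZooD"]], ] <- loss[PIDX[["w.ZooD"]], ] + zoo_resp
  loss[PIDX_O2, ] <- loss[PIDX_O2, ] + y_o2 * zoo_resp

  # --- fish ------------------------------------------------------------------
  f_t_fish <- temp_factor_biotic(temp, pv[["fish_topt"]], pv[["fish_tsig"]])
  ef <- pv[["fish_assim"]]
  predate <- function(pred, prey_w, prey_dm, prey_n, prey_p, intake_dm) {
    pds <- pmax.int(prey_dm, 1e-12)
    qn <- prey_n / pds; qp <- prey_p / pds
    trs(c(paste0("w.", pred, "D"), "w.POMD", paste0("w.", pred, "N"), "w.POMN",
          paste0("w.", pred, "P"), "w.POMP"),
        c(prey_w[1], prey_w[1], prey_w[2], prey_w[2], prey_w[3], prey_w[3]),
        rbind(ef * intake_dm, (1 - ef) * intake_dm,
              ef * intake_dm * qn, (1 - ef) * intake_dm * qn,
              ef * intake_dm * qp, (1 - ef) * intake_dm * qp))
  }
  zoo_dm <- w[iW$ZooD, ]
  # weed beds shelter zooplankton from visually hunting juveniles
  refuge <- 1 - pv[["zoo_refuge"]] * cover / 100
  intake_jv <- pv[["fjv_upt"]] * f_t_fish * refuge *
    zoo_dm / (zoo_dm + pv[["fjv_hzoo"]]) * w[iW$FJvD, ] * vol
  predate("FJv", c("w.ZooD", "w.ZooN", "w.ZooP"), zoo_dm,
          w[iW$ZooN, ], w[iW$ZooP, ], intake_jv)
  ben_dm <- s[iS$BenD, ]
  intake_ad <- pv[["fad_upt"]] * f_t_fish * ben_dm / (ben_dm + pv[["fad_hben"]]) *
    w[iW$FAdD, ] * vol
  predate("FAd", c("s.BenD", "s.BenN", "s.BenP"), ben_dm,
          s[iS$BenN, ], s[iS$BenP, ], intake_ad)
  f_cov <- pv[["c_cov_veg_min"]] +
    (1 - pv[["c_cov_veg_min"]]) * cover / (cover + pv[["h_d_veg_pisc"]])
  prey_tot <- w[iW$FJvD, ] + w[iW$FAdD, ]
  intake_pi <- pv[["fpi_upt"]] * f_t_fish * f_cov *
    prey_tot / (prey_tot + pv[["fpi_hprey"]]) * w[iW$FPiD, ] * vol
  shr <- w[iW$FJvD, ] / pmax.int(prey_tot, 1e-12)
  predate("FPi", c("w.FJvD", "w.FJvN", "w.FJvP"), w[iW$FJvD, ],
          w[iW$FJvN, ], w[iW$FJvP, ], intake_pi * shr)
  predate("FPi", c("w.FAdD", "w.FAdN", "w.FAdP"), w[iW$FAdD, ],
          w[iW$FAdN, ], w[iW$FAdP, ], intake_pi * (1 - shr))
  fr <- pv[["fish_resp"]] * th_min
  fm <- pv[["fish_mort"]]
  for (g in c("FJv", "FAd", "FPi")) {
    kk <- FISH_KEYS[[g]]
    resp <- fr * w[kk$iD, ] * vol
    loss[kk$pD, ] <- loss[kk$pD, ] + resp
    loss[PIDX_O2, ] <- loss[PIDX_O2, ] + y_o2 * resp
    trs(c("w.NH4", "w.PO4", "w.POMD", "w.POMN", "w.POMP"),
        c(kk$wN, kk$wP, kk$wD, kk$wN, kk$wP),
        rbind(fr * w[kk$iN, ] * vol, fr * w[kk$iP, ] * vol,
              fm * w[kk$iD, ] * vol, fm * w[kk$iN, ] * vol,
              fm * w[kk$iP, ] * vol))
  }

  # --- water-column organic matter and nutrients -----------------------------
  hyd <- pv[["k_hyd_pom"]] * th_min
  pom_min <- hyd * w[iW$POMD, ] * vol
  dom_min_n <- pv[["k_min_dom"]] * th_min * w[iW$DON, ] * vol
  dom_min_p <- pv[["k_min_dom"]] * th_min * w[iW$DOP, ] * vol
  nit <- pv[["k_nit_w"]] * th_nit * o2 / (o2 + pv[["h_nit_o2"]]) * w[iW$NH4, ] * vol
  den_w <- pv[["k_den_w"]] * th_den * pv[["h_anox"]] / (o2 + pv[["h_anox"]]) *
    w[iW$NO3, ] * vol
  trs(c("w.DON", "w.DOP", "w.NH4", "w.PO4", "w.NO3", "N2"),
      c("w.POMN", "w.POMP", "w.DON", "w.DOP", "w.NH4", "w.NO3"),
      rbind(hyd * w[iW$POMN, ] * vol, hyd * w[iW$POMP, ] * vol,
            dom_min_n, dom_min_p, nit, den_w))
  loss[PIDX[["w.POMD"]], ] <- loss[PIDX[["w.POMD"]], ] + pom_min
  loss[PIDX_O2, ] <- loss[PIDX_O2, ] + y_o2 * pom_min +
    y_o2 * pv[["dm_per_n"]] * dom_min_n + pv[["y_o2_nit"]] * nit

  # reaeration, top layer only (split so both directions stay positive)
  k_rea <- (pv[["rea_k0"]] + pv[["rea_kwind"]] * frc$wind^2) *
    temp_factor_abiotic(temp[n], pv[["theta_rea"]])
  src[PIDX_O2, n] <- src[PIDX_O2, n] +
    k_rea * o2_saturation(temp[n]) * grid$surface_area
  loss[PIDX_O2, n] <- loss[PIDX_O2, n] + k_rea * grid$surface_area * o2[n]

  # --- sediment --------------------------------------------------------------
  pore_vol <- pv[["h_sed"]] * pv[["porosity"]]
  f_oxic <- o2 / (o2 + pv[["h_oxic"]])
  f_o2min <- 0.3 + 0.7 * f_oxic
  k_hum <- pv[["k_hum"]]
  min_sed <- pv[["k_min_sed"]] * th_min * f_o2min
  min_hum <- pv[["k_min_hum"]] * th_min * f_o2min
  sed_pomd_min <- min_sed * s[iS$POMD, ] * ben
  hum_d_min <- min_hum * s[iS$HumD, ] * ben
  nit_s <- pv[["k_nit_sed"]] * th_nit * o2 / (o2 + pv[["h_nit_o2"]]) *
    s[iS$NH4, ] * ben
  den_s <- pv[["k_den_sed"]] * th_den * pv[["h_anox"]] / (o2 + pv[["h_anox"]]) *
    s[iS$NO3, ] * ben
  trs(c("s.HumD", "s.HumN", "s.HumP", "s.NH4", "s.PO4", "s.NH4", "s.PO4",
        "s.NO3", "N2"),
      c("s.POMD", "s.POMN", "s.POMP", "s.POMN", "s.POMP", "s.HumN", "s.HumP",
        "s.NH4", "s.NO3"),
      rbind(k_hum * s[iS$POMD, ] * ben, k_hum * s[iS$POMN, ] * ben,
            k_hum * s[iS$POMP, ] * ben,
            min_sed * s[iS$POMN, ] * ben, min_sed * s[iS$POMP, ] * ben,
            min_hum * s[iS$HumN, ] * ben, min_hum * s[iS$HumP, ] * ben,
            nit_s, den_s))
  loss[PIDX[["s.POMD"]], ] <- loss[PIDX[["s.POMD"]], ] + sed_pomd_min
  loss[PIDX[["s.HumD"]], ] <- loss[PIDX[["s.HumD"]], ] + hum_d_min
  loss[PIDX_O2, ] <- loss[PIDX_O2, ] + y_o2 * (sed_pomd_min + hum_d_min) +
    pv[["y_o2_nit"]] * nit_s

  # porewater <-> water diffusion
  kdif <- pv[["k_dif"]] * th_dif
  fl_nh4 <- kdif * (s[iS$NH4, ] / pore_vol - w[iW$NH4, ]) * ben
  fl_no3 <- kdif * (s[iS$NO3, ] / pore_vol - w[iW$NO3, ]) * ben
  fl_po4 <- kdif * (s[iS$PO4, ] / pore_vol - w[iW$PO4, ]) * ben
  # P sorption to iron-bound inorganic matter (PAIMS), oxic-dependent
  cp_po4 <- s[iS$PO4, ] / pore_vol
  paims_max <- pv[["q_ads_max"]] * pv[["fe_frac"]] * s[iS$IM, ]
  paims_eq <- paims_max * f_oxic * pv[["k_lang"]] * cp_po4 /
    (1 + pv[["k_lang"]] * cp_po4)
  sorp <- pv[["k_sorp"]] * (paims_eq - s[iS$PAIMS, ]) * ben   # g/d
  # resuspension (damped by macrophyte coverage)
  res <- pv[["k_resus"]] * pmax.int(0, tau_shear - pv[["tau_crit"]]) *
    (1 - pv[["f_veg_res"]] * cover / 100)
  kb <- pv[["k_bury"]]
  trs(c("w.NH4", "s.NH4", "w.NO3", "s.NO3", "w.PO4", "s.PO4",
        "s.PAIMS", "s.PO4",
        "w.POMD", "w.POMN", "w.POMP", "w.IM",
        "BURN", "BURN", "BURP", "BURP", "BURP"),
      c("s.NH4", "w.NH4", "s.NO3", "w.NO3", "s.PO4", "w.PO4",
        "s.PO4", "s.PAIMS",
        "s.POMD", "s.POMN", "s.POMP", "s.IM",
        "s.POMN", "s.HumN", "s.POMP", "s.HumP", "s.PAIMS"),
      rbind(pmax.int(fl_nh4, 0), pmax.int(-fl_nh4, 0),
            pmax.int(fl_no3, 0), pmax.int(-fl_no3, 0),
            pmax.int(fl_po4, 0), pmax.int(-fl_po4, 0),
            pmax.int(sorp, 0), pmax.int(-sorp, 0),
            res * s[iS$POMD, ] * ben, res * s[iS$POMN, ] * ben,
            res * s[iS$POMP, ] * ben, res * s[iS$IM, ] * ben,
            kb * s[iS$POMN, ] * ben, kb * s[iS$HumN, ] * ben,
            kb * s[iS$POMP, ] * ben, kb * s[iS$HumP, ] * ben,
            kb * s[iS$PAIMS, ] * ben))
  loss[PIDX[["s.POMD"]], ] <- loss[PIDX[["s.POMD"]], ] + kb * s[iS$POMD, ] * ben
  loss[PIDX[["s.HumD"]], ] <- loss[PIDX[["s.HumD"]], ] + kb * s[iS$HumD, ] * ben
  loss[PIDX[["s.IM"]], ] <- loss[PIDX[["s.IM"]], ] + kb * s[iS$IM, ] * ben

  # zoobenthos
  f_t_ben <- temp_factor_biotic(temp, pv[["ben_topt"]], pv[["ben_tsig"]])
  eb <- pv[["ben_assim"]]
  intake_b <- pv[["ben_upt"]] * f_t_ben * s[iS$POMD, ] /
    (s[iS$POMD, ] + pv[["ben_hpom"]]) * s[iS$BenD, ] * ben
  spomds <- pmax.int(s[iS$POMD, ], 1e-12)
  br <- pv[["ben_resp"]] * th_min
  bm <- pv[["ben_mort"]]
  trs(c("s.BenD", "s.BenN", "s.BenP", "s.NH4", "s.PO4",
        "s.POMD", "s.POMN", "s.POMP"),
      c("s.POMD", "s.POMN", "s.POMP", "s.BenN", "s.BenP",
        "s.BenD", "s.BenN", "s.BenP"),
      rbind(eb * intake_b, eb * intake_b * s[iS$POMN, ] / spomds,
            eb * intake_b * s[iS$POMP, ] / spomds,
            br * s[iS$BenN, ] * ben, br * s[iS$BenP, ] * ben,
            bm * s[iS$BenD, ] * ben, bm * s[iS$BenN, ] * ben,
            bm * s[iS$BenP, ] * ben))
  ben_resp <- br * s[iS$BenD, ] * ben
  loss[PIDX[["s.BenD"]], ] <- loss[PIDX[["s.BenD"]], ] + ben_resp
  loss[PIDX_O2, ] <- loss[PIDX_O2, ] + y_o2 * ben_resp

  # macrophytes (rooted; light from the bottom of their layer, nutrients from
  # porewater)
  npore <- (s[iS$NH4, ] + s[iS$NO3, ]) / pore_vol
  # roots mine the whole sedimentary P stock: porewater, iron-bound (PAIMS)
  # and organic-bound P, so rooted plants are nutrient-limited only when the
  # sediment is truly exhausted
  p_stock <- s[iS$PO4, ] + s[iS$PAIMS, ] + s[iS$POMP, ] + s[iS$HumP, ]
  p_access <- p_stock / pore_vol
  f_nut <- pmin.int(npore / (npore + pv[["veg_hn"]]),
                    p_access / (p_access + pv[["veg_hp"]]))
  # a propagule bank (seeds, turions, bird-dispersed fragments) germinates
  # under the same environmental controls, so colonisation restarts whenever
  # light returns to the bed
  # the canopy harvests light above its own shade: discount the bed PAR by
  # the stand's own within-layer attenuation (never beyond the layer top)
  par_veg <- pmin.int(lp$par_bottom * exp(pv[["k_veg"]] * s[iS$VegD, ]),
                      lp$par_top)
  # threshold-like (Hill) light response: the annual carbon balance of an
  # overwintering perennial is near-binary around its compensation light
  f_l_veg <- par_veg^2 / (par_veg^2 + pv[["veg_hpar"]]^2)
  veg_prod <- (s[iS$VegD, ] + pv[["veg_seed_b"]]) * pv[["veg_pmax"]] *
    exp(pv[["veg_cprod"]] * (temp - 20)) * f_l_veg *
    pmax.int(0, 1 - s[iS$VegD, ] / pv[["veg_bmax"]]) * f_nut * ben
  rspec <- pv[["veg_resp"]] * exp(pv[["veg_cresp"]] * (temp - 20))
  veg_resp <- rspec * s[iS$VegD, ] * ben
  src[PIDX[["s.VegD"]], ] <- src[PIDX[["s.VegD"]], ] + veg_prod
  src[PIDX_O2, ] <- src[PIDX_O2, ] + y_o2 * veg_prod
  loss[PIDX[["s.VegD"]], ] <- loss[PIDX[["s.VegD"]], ] + veg_resp
  loss[PIDX_O2, ] <- loss[PIDX_O2, ] + y_o2 * veg_resp
  up_veg_n <- veg_prod * pv[["veg_qn"]]
  sh_s <- nh4_share(s[iS$NH4, ], s[iS$NO3, ], pv[["pref_nh4"]])
  # background mortality plus wave scour on the standing canopy: shoots are
  # present in proportion to light-driven activity, so overwintering organs
  # below the bed escape the waves
  vm <- pv[["veg_mort"]] + pv[["veg_wave_mort"]] * tau_shear * f_l_veg
  ps <- pmax.int(p_stock, 1e-12)
  # shoots take a share of the nutrient demand straight from the water
  # column (competition with phytoplankton); roots supply the rest
  fsh <- pv[["veg_shoot_frac"]]
  up_veg_p <- veg_prod * pv[["veg_qp"]]
  up_p_root <- (1 - fsh) * up_veg_p
  sh_w <- nh4_share(w[iW$NH4, ], w[iW$NO3, ], pv[["pref_nh4"]])
  trs(c("s.VegN", "s.VegN", "s.VegN", "s.VegN",
        "s.VegP", "s.VegP", "s.VegP", "s.VegP", "s.VegP",
        "s.NH4", "s.PO4", "s.POMD", "s.POMN", "s.POMP"),
      c("s.NH4", "s.NO3", "w.NH4", "w.NO3",
        "s.PO4", "s.PAIMS", "s.POMP", "s.HumP", "w.PO4",
        "s.VegN", "s.VegP", "s.VegD", "s.VegN", "s.VegP"),
      rbind((1 - fsh) * up_veg_n * sh_s, (1 - fsh) * up_veg_n * (1 - sh_s),
            fsh * up_veg_n * sh_w, fsh * up_veg_n * (1 - sh_w),
            up_p_root * s[iS$PO4, ] / ps, up_p_root * s[iS$PAIMS, ] / ps,
            up_p_root * s[iS$POMP, ] / ps, up_p_root * s[iS$HumP, ] / ps,
            fsh * up_veg_p,
            rspec * s[iS$VegN, ] * ben, rspec * s[iS$VegP, ] * ben,
            vm * s[iS$VegD, ] * ben, vm * s[iS$VegN, ] * ben,
            vm * s[iS$VegP, ] * ben))

  # --- Modified Patankar update ---------------------------------------------
  if (first) {
    ti <- ti[seq_len(k_tr)]; tj <- tj[seq_len(k_tr)]
    cache$ti <- ti; cache$tj <- tj; cache$ntrip <- k_tr
    grp <- (ti - 1L) * NPOOL + tj
    ugrp <- sort(unique(grp))
    gmap <- match(grp, ugrp)
    cache$ui <- as.integer((ugrp - 1L) %/% NPOOL + 1L)
    cache$uj <- as.integer((ugrp - 1L) %% NPOOL + 1L)
    # indicator matrices: aggregate duplicate donor/receiver pairs and total
    # per-donor destruction with two BLAS products instead of rowsum()
    g_agg <- matrix(0, length(ugrp), k_tr)
    g_agg[cbind(gmap, seq_len(k_tr))] <- 1
    g_dest <- matrix(0, NPOOL, k_tr)
    g_dest[cbind(tj, seq_len(k_tr))] <- 1
    cache$g_agg <- g_agg; cache$g_dest <- g_dest
    rmat <- rmat[seq_len(k_tr), , drop = FALSE]
  }
  rmat[rmat < 0] <- 0
  agg <- cache$g_agg %*% rmat
  d_tot <- loss + cache$g_dest %*% rmat

  nw <- length(W_VARS); ns <- length(S_VARS)
  c_mat <- rbind(w * rep(vol, each = nw), s * rep(ben, each = ns),
                 matrix(0, 3, n))
  new_mat <- emp_solve_layers(c_mat, agg, cache$ui, cache$uj, d_tot, src, dt)
  w <- new_mat[seq_len(nw), , drop = FALSE] / rep(vol, each = nw)
  s <- new_mat[nw + seq_len(ns), , drop = FALSE] / rep(ben, each = ns)
  rownames(w) <- W_VARS; rownames(s) <- S_VARS
  led <- state$ledger
  led[["n2"]] <- led[["n2"]] + sum(new_mat[PIDX[["N2"]], ])
  led[["bur_n"]] <- led[["bur_n"]] + sum(new_mat[PIDX[["BURN"]], ])
  led[["bur_p"]] <- led[["bur_p"]] + sum(new_mat[PIDX[["BURP"]], ])

  # --- transport: inflow, outflow, settling, mixing --------------------------
  q_dt <- frc$q_in * dt                          # m^3 this step
  load_p <- load_n <- 0
  if (q_dt > 0) {
    fdom <- pv[["f_org_in_dom"]]
    # live plankton inoculum carried by the inlets, carved out of the organic
    # load so total N and P loads are unchanged
    sd_phy <- pv[["phyto_seed_in"]]; sd_zoo <- pv[["zoo_seed_in"]]
    seed_n <- (3 * sd_phy + sd_zoo) * 0.04
    seed_p <- (3 * sd_phy + sd_zoo) * 0.006
    pom_n_in <- max((1 - fdom) * frc$c_orgn - seed_n, 0)
    pom_p_in <- max((1 - fdom) * frc$c_orgp - seed_p, 0)
    inn <- c(NH4 = frc$c_nh4, NO3 = frc$c_no3, PO4 = frc$c_po4,
             DON = fdom * frc$c_orgn, POMN = pom_n_in,
             DOP = fdom * frc$c_orgp, POMP = pom_p_in,
             POMD = pom_n_in / pv[["n_per_dm_pom"]],
             DiaD = sd_phy, DiaN = sd_phy * 0.04, DiaP = sd_phy * 0.006,
             CyaD = sd_phy, CyaN = sd_phy * 0.04, CyaP = sd_phy * 0.006,
             OthD = sd_phy, OthN = sd_phy * 0.04, OthP = sd_phy * 0.006,
             ZooD = sd_zoo, ZooN = sd_zoo * 0.04, ZooP = sd_zoo * 0.006)
    w[names(inn), n] <- w[names(inn), n] + inn * q_dt / vol[n]
    load_n <- (frc$c_nh4 + frc$c_no3 + frc$c_orgn) * q_dt
    load_p <- (frc$c_po4 + frc$c_orgp) * q_dt
    led[["in_n"]] <- led[["in_n"]] + load_n
    led[["in_p"]] <- led[["in_p"]] + load_p
    # outflow keeps the level constant; fish hold station and are not flushed
    f_out <- 1 - exp(-q_dt / vol[n])
    led[["out_n"]] <- led[["out_n"]] + f_out * vol[n] * sum(w[FLUSH_N_IDX, n])
    led[["out_p"]] <- led[["out_p"]] + f_out * vol[n] * sum(w[FLUSH_P_IDX, n])
    w[FLUSH_IDX, n] <- w[FLUSH_IDX, n] * (1 - f_out)
  }

  # settling (implicit downward sweep over all settling tracers at once,
  # depositing on each layer's benthic area)
  ifa <- grid$interface_areas
  vs <- c(pv[["settle_pom"]], pv[["settle_pom"]], pv[["settle_pom"]],
          pv[["settle_im"]],
          pv[["settle_dia"]], pv[["settle_dia"]], pv[["settle_dia"]],
          pv[["settle_cya"]], pv[["settle_cya"]], pv[["settle_cya"]],
          pv[["settle_oth"]], pv[["settle_oth"]], pv[["settle_oth"]])
  cw <- w[SETTLE_SRC_IDX, , drop = FALSE]
  dep <- matrix(0, length(vs), n)
  in_above <- numeric(length(vs))
  for (k in n:1) {
    cnew <- (cw[, k] * vol[k] + in_above) / (vol[k] + dt * vs * ifa[k + 1])
    dep[, k] <- dt * vs * cnew * grid$benthic_areas[k]
    if (k > 1) in_above <- dt * vs * cnew * ifa[k]
    cw[, k] <- cnew
  }
  w[SETTLE_SRC_IDX, ] <- cw
  dep_per_area <- sweep(dep, 2, ben, "/")
  for (jj in seq_along(SETTLE_DEST_ROWS)) {
    s[SETTLE_DEST_ROWS[jj], ] <- s[SETTLE_DEST_ROWS[jj], ] + dep_per_area[jj, ]
  }

  # vertical mixing of all water-column pools and heat
  if (n > 1) {
    op <- mixing_operator(grid, pv[["mix_d0"]] + pv[["mix_cw"]] * frc$wind^3, dt)
    w <- op(w)
    temp <- as.numeric(op(rbind(temp)))
    rownames(w) <- W_VARS
  }

  state$water <- w; state$sed <- s; state$temp <- temp
  state$ledger <- led
  state$day <- state$day + dt

  # --- diagnostics -----------------------------------------------------------
  chl <- chla(w[paste0(PHYTO_GROUPS, "D"), , drop = FALSE], f_light_grp,
              chl_min = c(pv[["chl_dm_min_dia"]], pv[["chl_dm_min_cya"]],
                          pv[["chl_dm_min_oth"]]),
              chl_max = c(pv[["chl_dm_max_dia"]], pv[["chl_dm_max_cya"]],
                          pv[["chl_dm_max_oth"]]))
  cover_new <- 100 * (1 - exp(-s[iS$VegD, ] / pv[["b_cov"]]))
  lake_cover <- sum(cover_new * grid$benthic_areas) / sum(grid$benthic_areas)
  ok <- which(cover_new >= 0.1)
  depth_limit <- if (length(ok)) grid$max_depth - grid$interfaces[min(ok)] else 0
  list(state = state,
       diag = list(chl_total = chl$total, chl_group = chl$per_group,
                   par_mean = lp$par_mean, par_bottom = lp$par_bottom,
                   kd = lp$kd, cover = cover_new,
                   lake_cover = lake_cover,
                   depth_limit = depth_limit,
                   load_p = load_p, load_n = load_n,
                   gross_prod = gross_prod_dm))
}
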