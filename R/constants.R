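# state-vector layout ---------------------------------------------------------
# water-column pools, concentrations in g/m^3, one column per layer (1 = bottom)
W_VARS <- c("NH4", "NO3", "PO4", "DON", "DOP", "POMD", "POMN", "POMP", "IM",
            "O2",
            "DiaD", "DiaN", "DiaP", "CyaD", "CyaN", "CyaP",
            "OthD", "OthN", "OthP",
            "ZooD", "ZooN", "ZooP",
            "FJvD", "FJvN", "FJvP", "FAdD", "FAdN", "FAdP",
            "FPiD", "FPiN", "FPiP")
# sediment pools, areal g/m^2 of benthic area (PAIMS is adsorbed P; NH4/NO3/PO4
# are porewater stocks per m^2)
S_VARS <- c("POMD", "POMN", "POMP", "HumD", "HumN", "HumP", "IM", "PAIMS",
            "NH4", "NO3", "PO4", "BenD", "BenN", "BenP",
            "VegD", "VegN", "VegP")

W_N_POOLS <- c("NH4", "NO3", "DON", "POMN", "DiaN", "CyaN", "OthN", "ZooN",
               "FJvN", "FAdN", "FPiN")
W_P_POOLS <- c("PO4", "DOP", "POMP", "DiaP", "CyaP", "OthP", "ZooP",
               "FJvP", "FAdP", "FPiP")
S_N_POOLS <- c("POMN", "HumN", "NH4", "NO3", "BenN", "VegN")
S_P_POOLS <- c("POMP", "HumP", "PAIMS", "PO4", "BenP", "VegP")

# combined per-layer pool order for the production-destruction system
ALL_POOLS <- c(paste0("w.", W_VARS), paste0("s.", S_VARS), "N2", "BURN", "BURP")
PIDX <- stats::setNames(seq_along(ALL_POOLS), ALL_POOLS)
NPOOL <- length(ALL_POOLS)

PHYTO_GROUPS <- c("Dia", "Cya", "Oth")

# integer row-index maps for fast state access in the inner loop
iW <- as.list(stats::setNames(seq_along(W_VARS), W_VARS))
iS <- as.list(stats::setNames(seq_along(S_VARS), S_VARS))

# outflow flushes all water pools except fish (they hold station)
FLUSH_IDX <- which(!startsWith(W_VARS, "F"))
FLUSH_N_IDX <- which(W_VARS %in% W_N_POOLS & !startsWith(W_VARS, "F"))
FLUSH_P_IDX <- which(W_VARS %in% W_P_POOLS & !startsWith(W_VARS, "F"))

PIDX_O2 <- PIDX[["w.O2"]]

# precomputed per-group state indices and parameter keys for the hot loop
PHY_KEYS <- lapply(stats::setNames(PHYTO_GROUPS, PHYTO_GROUPS), function(g) {
  gl <- tolower(g)
  list(iD = iW[[paste0(g, "D")]], iN = iW[[paste0(g, "N")]],
       iP = iW[[paste0(g, "P")]],
       wD = paste0("w.", g, "D"), wN = paste0("w.", g, "N"),
       wP = paste0("w.", g, "P"),
       pD = PIDX[[paste0("w.", g, "D")]],
       mu_max = paste0("mu_max_", gl), t_opt = paste0("t_opt_", gl),
       t_sig = paste0("t_sig_", gl), h_par = paste0("h_par_", gl),
       v_max_p = paste0("v_max_p_", gl), k_p_upt = paste0("k_p_upt_", gl))
})
FISH_KEYS <- lapply(stats::setNames(c("FJv", "FAd", "FPi"),
                                    c("FJv", "FAd", "FPi")), function(g) {
  list(iD = iW[[paste0(g, "D")]], iN = iW[[paste0(g, "N")]],
       iP = iW[[paste0(g, "P")]],
       wD = paste0("w.", g, "D"), wN = paste0("w.", g, "N"),
       wP = paste0("w.", g, "P"),
       pD = PIDX[[paste0("w.", g, "D")]])
})

# settling tracers (order matches the velocity vector in the transport step)
SETTLE_SRC <- c("POMD", "POMN", "POMP", "IM",
                "DiaD", "DiaN", "DiaP", "CyaD", "CyaN", "CyaP",
                "OthD", "OthN", "OthP")
SETTLE_SRC_IDX <- match(SETTLE_SRC, W_VARS)
SETTLE_DEST_ROWS <- match(c("POMD", "POMN", "POMP", "IM",
                            rep(c("POMD", "POMN", "POMP"), 3)), S_VARS)
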