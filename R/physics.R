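#' Daily mean surface photosynthetically active radiation
#'
#' Clear-sky daily mean shortwave from solar geometry (extraterrestrial
#' radiation for the day of year and latitude, times an atmospheric
#' transmissivity), reduced by cloud cover as `(1 - 0.7 * cloud)`; PAR is
#' taken as 50% of shortwave.
#'
#' @param doy Day of year (1-365; fractional allowed).
#' @param cloud Cloud cover fraction in `[0, 1]`.
#' @param latitude Latitude in degrees (default 56, Jutland).
#' @param transmissivity Clear-sky atmospheric transmissivity.
#' @return Tibble with `swr_wm2` and `par_wm2` (daily means, W/m^2).
#' @export
surface_par <- function(doy, cloud = 0, latitude = 56, transmissivity = 0.7) {
  assert_that(all(cloud >= 0 & cloud <= 1), "cloud must be in [0,1]")
  gsc <- 1367                       # solar constant W/m^2
  phi <- latitude * pi / 180
  dr <- 1 + 0.033 * cos(2 * pi * doy / 365)
  delta <- 0.409 * sin(2 * pi * doy / 365 - 1.39)
  x <- clamp(-tan(phi) * tan(delta), -1, 1)
  ws <- acos(x)                     # sunset hour angle
  # daily mean extraterrestrial radiation, W/m^2
  ra <- (gsc / pi) * dr * (ws * sin(phi) * sin(delta) + cos(phi) * cos(delta) * sin(ws))
  swr <- pmax(0, ra * transmissivity * (1 - 0.7 * cloud))
  tibble::tibble(swr_wm2 = swr, par_wm2 = 0.5 * swr)
}

#' Light attenuation through the water column
#'
#' Lambert-Beer attenuation with a per-layer extinction coefficient
#' `K_d = K_bg + sum_i k_i * C_i` built from phytoplankton dry mass,
#' particulate organic matter, suspended inorganic matter, and an areal
#' macrophyte shading term. Returns PAR at the top and bottom interface of
#' every layer and the depth-averaged PAR inside each layer; the
#' bottom-of-layer PAR is what rooted macrophytes on that layer's sediment
#' receive.
#'
#' @param surface_par Surface PAR (W/m^2, scalar).
#' @param grid A `lake_grid` (layer 1 = bottom).
#' @param phyto_dm Per-layer phytoplankton dry mass, either a vector
#'   (g/m^3) attenuated with `k_phyto`, or a matrix (groups x layers) with
#'   `k_phyto` a per-group vector.
#' @param pom Per-layer POM dry mass (g/m^3).
#' @param im Per-layer suspended inorganic matter (g/m^3).
#' @param veg Per-layer macrophyte biomass (g/m^2 of benthic area),
#'   converted to a within-layer attenuation via `k_veg * veg / height`.
#' @param k_bg,k_phyto,k_pom,k_im,k_veg Extinction coefficients
#'   (1/m background; m^2/g otherwise).
#' @return Tibble, bottom layer first: `layer`, `kd` (1/m), `par_top`,
#'   `par_mean`, `par_bottom` (W/m^2).
#' @export
light_profile <- function(surface_par, grid, phyto_dm = 0, pom = 0, im = 0,
                          veg = 0, k_bg = 0.5, k_phyto = 0.1, k_pom = 0.05,
                          k_im = 0.05, k_veg = 0.01) {
  n <- grid$n_layers
  if (is.matrix(phyto_dm)) {
    assert_that(all(phyto_dm >= 0), "concentrations must be non-negative")
    phy_att <- as.numeric(k_phyto %*% phyto_dm)
  } else {
    phy_att <- k_phyto * rep_len(phyto_dm, n)
  }
  pom <- rep_len(pom, n); im <- rep_len(im, n); veg <- rep_len(veg, n)
  assert_that(all(c(phy_att, pom, im, veg) >= 0),
              "concentrations must be non-negative")
  kd <- k_bg + phy_att + k_pom * pom + k_im * im + k_veg * veg / grid$heights
  # integrate from the surface (layer n) downwards
  tau <- kd * grid$heights                       # optical thickness per layer
  tau_above <- rev(cumsum(rev(tau)))             # surface to bottom of layer k
  par_bottom <- surface_par * exp(-tau_above)
  par_top <- surface_par * exp(-(tau_above - tau))
  par_mean <- ifelse(tau > 1e-12, (par_top - par_bottom) / tau, par_top)
  tibble::tibble(layer = seq_len(n), kd = kd, par_top = par_top,
                 par_mean = par_mean, par_bottom = par_bottom)
}

#' Water temperature by relaxation towards a meteorological equilibrium
#'
#' In place of a turbulence-closure heat budget, each layer relaxes
#' towards an equilibrium temperature `T_eq = max(0, T_air + c_swr * SWR)`
#' with a time constant that grows with depth, damping the annual
#' amplitude at the bottom; vertical mixing then homogenises the column,
#' so shallow grids behave polymictically. Water temperature is clamped at
#' 0 degC (no ice module).
#'
#' @param temp Per-layer temperature (degC), layer 1 = bottom.
#' @param air_temp Air temperature (degC) for this step.
#' @param swr Shortwave radiation (W/m^2) for this step.
#' @param grid A `lake_grid`.
#' @param dt Time step (d).
#' @param tau0 Surface relaxation time (d).
#' @param z_tau Depth scale (m) over which the relaxation slows.
#' @param c_swr Radiative warming coefficient (degC per W/m^2).
#' @return Updated per-layer temperature vector.
#' @export
water_temperature_step <- function(temp, air_temp, swr, grid, dt,
                                   tau0 = 4, z_tau = 4, c_swr = 0.045) {
  t_eq <- pmax(0, air_temp + c_swr * swr)
  tau <- tau0 * (1 + grid$depths / z_tau)
  # exact solution of linear relaxation over dt
  pmax(0, t_eq + (temp - t_eq) * exp(-dt / tau))
}

# implicit diffusion matrix for one step; returns function(conc) -> mixed conc
# conservative in volume-weighted mass for any diffusivity
mixing_operator <- function(grid, diffusivity, dt) {
  n <- grid$n_layers
  if (n == 1) return(function(conc) conc)
  v <- grid$volumes
  a_int <- grid$interface_areas[2:n]                 # internal interfaces
  dz <- (grid$heights[1:(n - 1)] + grid$heights[2:n]) / 2
  g <- dt * diffusivity * a_int / dz                 # m^3 exchanged
  m <- diag(v)
  k <- 1:(n - 1)
  m[cbind(k, k)] <- m[cbind(k, k)] + g
  m[cbind(k + 1, k + 1)] <- m[cbind(k + 1, k + 1)] + g
  m[cbind(k, k + 1)] <- -g
  m[cbind(k + 1, k)] <- -g
  function(conc) {
    if (is.matrix(conc)) t(solve(m, t(conc * rep(v, each = nrow(conc)))))
    else solve(m, conc * v)
  }
}

#' Conservative implicit vertical mixing
#'
#' Mixes a tracer column by implicit diffusion with a wind-parameterised
#' diffusivity `D = D0 + c_w * wind^3`. The update is unconditionally
#' stable, conserves volume-weighted tracer mass to machine precision, and
#' is contractive (the layer-to-layer spread never grows).
#'
#' @param conc Per-layer tracer concentration (vector, layer 1 = bottom)
#'   or a matrix with layers as columns (each row a tracer).
#' @param grid A `lake_grid`.
#' @param wind_speed Wind speed (m/s).
#' @param dt Time step (d).
#' @param d0 Background diffusivity (m^2/d).
#' @param c_w Wind-cubed diffusivity coefficient (m^2/d per (m/s)^3).
#' @return Mixed concentration(s), same shape as `conc`.
#' @export
vertical_mixing <- function(conc, grid, wind_speed, dt, d0 = 0.5, c_w = 0.5) {
  assert_that(dt > 0, "dt must be positive")
  op <- mixing_operator(grid, d0 + c_w * wind_speed^3, dt)
  op(conc)
}

#' Wind-driven bottom shear proxy
#'
#' Dimensionless resuspension forcing that grows with the square of wind
#' speed and the square root of fetch and decays exponentially with depth
#' (wave energy reaching the bed). Equals 1 at the reference wind (5 m/s)
#' and fetch (1000 m) at zero depth.
#'
#' @param wind_speed Wind speed (m/s).
#' @param fetch Fetch length (m).
#' @param depth Depth of the bed below the surface (m).
#' @param w_ref,f_ref Reference wind (m/s) and fetch (m).
#' @param z_wave Depth decay scale (m).
#' @return Dimensionless shear proxy tau (>= 0).
#' @export
bottom_shear <- function(wind_speed, fetch, depth, w_ref = 5, f_ref = 1000,
                         z_wave = 1.5) {
  assert_that(all(wind_speed >= 0) && all(fetch >= 0) && all(depth >= 0),
              "inputs must be non-negative")
  (wind_speed / w_ref)^2 * sqrt(fetch / f_ref) * exp(-depth / z_wave)
}

#' Oxygen saturation concentration
#'
#' Freshwater oxygen saturation at surface pressure (APHA polynomial).
#'
#' @param temperature Water temperature (degC).
#' @return Saturation concentration (g O2/m^3).
#' @export
o2_saturation <- function(temperature) {
  t <- temperature
  14.652 - 0.41022 * t + 0.0079910 * t^2 - 0.000077774 * t^3
}

#' Surface reaeration flux
#'
#' Air-water oxygen exchange `k(wind) * theta^(T - 20) * (O2_sat(T) - O2)`:
#' positive (invasion) when the surface layer is undersaturated, negative
#' (outgassing) when supersaturated.
#'
#' @param o2 Surface oxygen concentration (g/m^3).
#' @param temperature Surface water temperature (degC).
#' @param wind_speed Wind speed (m/s).
#' @param k0 Still-air piston velocity (m/d).
#' @param k_wind Wind-squared piston coefficient (m/d per (m/s)^2).
#' @param theta Temperature multiplier base (exponential around 20 degC).
#' @return Flux in g O2 m^-2 d^-1 (positive into the lake).
#' @export
reaeration_flux <- function(o2, temperature, wind_speed, k0 = 0.4,
                            k_wind = 0.06, theta = 1.024) {
  assert_that(all(o2 >= 0), "o2 must be non-negative")
  k <- (k0 + k_wind * wind_speed^2) * theta^(temperature - 20)
  k * (o2_saturation(temperature) - o2)
}
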