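#' Multi-step-activation (Kuo-Bean-like) gating model
#'
#' An allosteric alternative to the independent-gate cube, used to check
#' that conclusions do not depend on model architecture. Four identical,
#' independent voltage sensors move between resting and activated positions
#' (horizontal transitions with binomial multiplicities 4,3,2,1 forward and
#' 1,2,3,4 backward); a final voltage-independent opening step requires all
#' four sensors up. Fast and slow inactivation are voltage-independent
#' particles whose on-rates are multiplied, and off-rates divided, by an
#' allosteric factor (`fast_allo`, `slow_allo`) per activated sensor, so
#' inactivation draws its voltage dependence equally from the four sensors.
#' Sensor transitions inside an inactivated tier are scaled by the same
#' factor (forward multiplied, backward divided), which preserves
#' microscopic reversibility on every loop by construction. The open state
#' carries the full allosteric weight of four activated sensors.
#'
#' The drug-free model has 24 states; [extend_with_drug()] doubles this to
#' 48 states and 224 directed transitions, with `CF` acting on the
#' fast-inactivation tier and `CS` on the slow tier (`CA` is not used by
#' this architecture). The channel conducts only in the open,
#' non-inactivated, unbound state.
#'
#' State names: `C0`..`C4` (sensors up) or `O` (open), with suffix `F` for
#' fast-inactivated, `S` for slow-inactivated, trailing `*` when
#' drug-bound.
#'
#' @param params Named list/vector: `sensor_open_A/Vhalf/r` and
#'   `sensor_close_A/Vhalf/r` (three-parameter rate laws of one sensor,
#'   saturating with depolarization resp. hyperpolarization), `open_rate`
#'   and `close_rate` (1/s, voltage-independent opening step), `fast_on`,
#'   `fast_off`, `fast_allo`, `slow_on`, `slow_off`, `slow_allo`.
#' @param drug Optional [drug_spec()]; when supplied the drug-bound layer is
#'   added immediately.
#' @return A `channel_model`.
#' @export
msa_model <- function(params, drug = NULL) {
  params <- as.list(params)
  need <- c(paste0("sensor_open_", c("A", "Vhalf", "r")),
            paste0("sensor_close_", c("A", "Vhalf", "r")),
            "open_rate", "close_rate",
            "fast_on", "fast_off", "fast_allo",
            "slow_on", "slow_off", "slow_allo")
  missing <- setdiff(need, names(params))
  if (length(missing)) {
    stop("missing MSA parameters: ", paste(missing, collapse = ", "),
         call. = FALSE)
  }
  fwd <- rate_law(params$sensor_open_A, params$sensor_open_Vhalf,
                  params$sensor_open_r, "depol")
  bwd <- rate_law(params$sensor_close_A, params$sensor_close_Vhalf,
                  params$sensor_close_r, "hyper")
  a <- params$fast_allo
  b <- params$slow_allo
  stopifnot(a > 0, b > 0)

  cfg <- tidyr::expand_grid(pos = 0:5, fi = c(FALSE, TRUE),
                            si = c(FALSE, TRUE))  # pos 5 = open
  base <- ifelse(cfg$pos == 5, "O", paste0("C", cfg$pos))
  states <- tibble(
    state = paste0(base, ifelse(cfg$fi, "F", ""), ifelse(cfg$si, "S", "")),
    conducting = cfg$pos == 5 & !cfg$fi & !cfg$si,
    pos = cfg$pos, fast_open = !cfg$fi, slow_open = !cfg$si)
  key <- function(pos, fi, si) {
    paste0(ifelse(pos == 5, "O", paste0("C", pos)),
           ifelse(fi, "F", ""), ifelse(si, "S", ""))
  }
  n_eff <- function(pos) pmin(pos, 4)

  rows <- list()
  add <- function(from, to, gate, dir, law, scale) {
    rows[[length(rows) + 1L]] <<- tibble(
      from = from, to = to, gate = gate, dir = dir,
      law = list(law), scale = scale)
  }
  for (fi in c(FALSE, TRUE)) {
    for (si in c(FALSE, TRUE)) {
      tier <- (if (fi) a else 1) * (if (si) b else 1)
      for (n in 0:3) {  # sensor steps
        add(key(n, fi, si), key(n + 1, fi, si), "sensor", "fwd",
            fwd, (4 - n) * tier)
        add(key(n + 1, fi, si), key(n, fi, si), "sensor", "bwd",
            bwd, (n + 1) / tier)
      }
      add(key(4, fi, si), key(5, fi, si), "opening", "open", NULL,
          params$open_rate)
      add(key(5, fi, si), key(4, fi, si), "opening", "close", NULL,
          params$close_rate)
    }
  }
  for (si in c(FALSE, TRUE)) {  # fast-inactivation particle
    for (pos in 0:5) {
      w <- a ^ n_eff(pos)
      add(key(pos, FALSE, si), key(pos, TRUE, si), "fast_inactivation",
          "close", NULL, params$fast_on * w)
      add(key(pos, TRUE, si), key(pos, FALSE, si), "fast_inactivation",
          "open", NULL, params$fast_off / w)
    }
  }
  for (fi in c(FALSE, TRUE)) {  # slow-inactivation gate
    for (pos in 0:5) {
      w <- b ^ n_eff(pos)
      add(key(pos, fi, FALSE), key(pos, fi, TRUE), "slow_inactivation",
          "close", NULL, params$slow_on * w)
      add(key(pos, fi, TRUE), key(pos, fi, FALSE), "slow_inactivation",
          "open", NULL, params$slow_off / w)
    }
  }
  model <- new_channel_model("msa", states, dplyr::bind_rows(rows), params)
  if (!is.null(drug)) model <- extend_with_drug(model, drug)
  model
}

#' Default calibrated MSA model
#'
#' The shipped MSA parameter set, tuned to the same behavioral constraint
#' set as the tetracube default (fast/slow recovery time constants, onset of
#' slow inactivation, gap recovery); agreement is qualitative by design.
#'
#' @param drug Optional [drug_spec()].
#' @return A `channel_model`.
#' @export
default_msa_model <- function(drug = NULL) {
  path <- system.file("extdata", "msa_default.yaml", package = "navblock")
  msa_model(read_model_config(path)$params, drug = drug)
}

#' Check the three architecture-independence observations
#'
#' Runs the qualitative checks that the headline conclusions do not depend
#' on model architecture: (1) the slowly-binding fast-inactivated-state
#' drug (`FI_sb`) shifts the steady-state slow-inactivation (`SInact_V`)
#' midpoint by more than 5 mV; (2) the fast-binding fast-inactivated-state
#' drug (`FI_fb`) produces a larger normalized sum-of-differences on the
#' slow-inactivation onset curve (`SInact_t`) than the slow-preferring
#' `SI_fb`; and (3) `FI_sb` is at least as effective as the
#' slow-inactivated-state-preferring drugs in delaying recovery (`Rec_t`).
#'
#' @param model A drug-free `channel_model` (tetracube or MSA).
#' @param drugs Prototype drugs, as from [prototype_drugs()].
#' @param grid_points Sweep-grid density, points per decade (durations) /
#'   mV step (voltages) passed through to [standard_protocol()].
#' @return A tibble with columns `observation`, `value`, `holds`.
#' @export
verify_architecture_independence <- function(model,
                                             drugs = prototype_drugs(),
                                             grid_points = 6) {
  sv <- standard_protocol("SInact_V", points_per_decade = grid_points)
  st <- standard_protocol("SInact_t", points_per_decade = grid_points)
  rt <- standard_protocol("Rec_t", points_per_decade = grid_points)

  sv_fit <- function(drug) {
    res <- run_sweep(model, sv, drug = drug)
    ctrl <- fit_boltzmann(dplyr::filter(res, .data$condition == "control"))
    drg <- fit_boltzmann(dplyr::filter(res, .data$condition == "drug"))
    drg$Vhalf - ctrl$Vhalf
  }
  shift <- sv_fit(drugs$FI_sb)

  nsods <- function(proto) {
    vapply(drugs[c("FI_fb", "FI_sb", "SI_fb", "SI_sb")], function(d) {
      nsod(run_sweep(model, proto, drug = d))
    }, numeric(1))
  }
  n_st <- nsods(st)
  n_rt <- nsods(rt)

  tibble(
    observation = c(
      "FI_sb shifts SInact_V midpoint by > 5 mV",
      "FI_fb nSOD(SInact_t) exceeds SI_fb",
      "FI_sb nSOD(Rec_t) >= both SI drugs"),
    value = c(shift, n_st[["FI_fb"]] - n_st[["SI_fb"]],
              n_rt[["FI_sb"]] - max(n_rt[["SI_fb"]], n_rt[["SI_sb"]])),
    holds = c(shift < -5, n_st[["FI_fb"]] > n_st[["SI_fb"]],
              n_rt[["FI_sb"]] >= max(n_rt[["SI_fb"]], n_rt[["SI_sb"]])))
}
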