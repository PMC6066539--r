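# Derivation of chlorophyll-fluorescence and gas-exchange parameters from raw
# readings, and memory-pattern classification of physiological parameters.
#
# Fluorescence nomenclature: Fs steady-state, Fm' light-adapted maximal, Fo
# dark-adapted minimal, Fm dark-adapted maximal, Fo' light-adapted minimal
# fluorescence; PPFD incident photon flux (umol photons m^-2 s^-1).

#' Derive photosynthetic parameters from raw readings
#'
#' Computes the standard quenching-analysis parameters from a set of
#' fluorescence and gas-exchange readings (vectorised over readings):
#' \itemize{
#'   \item `phiPSII = (Fm' - Fs) / Fm'` (PSII operating efficiency, Genty yield)
#'   \item `FvpFmp = (Fm' - Fo') / Fm'` (efficiency of open PSII centres)
#'   \item `qP = (Fm' - Fs) / (Fm' - Fo')` (photochemical quenching)
#'   \item `NPQ = Fm / Fm' - 1`
#'   \item `ETR = phiPSII * PPFD * psii_fraction * absorptance`
#'   \item `A_G = P_N + R_d` (gross assimilation)
#'   \item `phiCO2 = A_G / (PPFD * absorptance)`
#'   \item composite ratios `qE_ETR`, `phiPSII_phiCO2`, `ETR_AG`
#' }
#' When `Fo'` was not measured it is estimated as
#' `Fo / (Fv/Fm + Fo/Fm')` (Oxborough-Baker). The algebraic identity
#' `phiPSII = qP * FvpFmp` holds to numerical precision.
#'
#' @param reading Data frame (or list) with numeric fields `Fs`, `Fmp`, `Fo`,
#'   `Fm`, optional `Fop`, and `PPFD`.
#' @param gas Data frame (or list) with fields `P_N`, `g_s`, `E`, `C_i` and
#'   optionally `R_d` (dark respiration, default 0). May be `NULL` when only
#'   fluorescence parameters are wanted.
#' @param config A [run_config()] supplying `absorptance` and
#'   `psii_fraction`.
#' @param relaxed_Fmp Optional post-relaxation maximal fluorescence passed to
#'   [qe_partition()].
#' @return Data frame with one row per reading and one column per derived
#'   parameter.
#' @export
derive_fluorescence <- function(reading, gas = NULL, config = run_config(),
                                relaxed_Fmp = NULL) {
  r <- as.data.frame(reading, stringsAsFactors = FALSE)
  need <- c("Fs", "Fmp", "Fo", "Fm", "PPFD")
  missing_cols <- setdiff(need, names(r))
  if (length(missing_cols)) {
    stop("fluorescence reading lacks field(s): ",
         paste(missing_cols, collapse = ", "))
  }
  check_pair <- function(lhs, rhs, lab) {
    bad <- which(!(lhs <= rhs))
    if (length(bad)) {
      stop("fluorescence ordering violated (", lab, ") at reading ", bad[1])
    }
  }
  if (any(r$Fs <= 0)) stop("Fs must be positive")
  check_pair(r$Fs, r$Fmp, "Fs <= Fm'")
  check_pair(r$Fmp, r$Fm, "Fm' <= Fm")
  check_pair(r$Fo, r$Fs, "Fo <= Fs")

  fvfm <- (r$Fm - r$Fo) / r$Fm
  fop <- if ("Fop" %in% names(r) && !all(is.na(r$Fop))) {
    r$Fop
  } else {
    r$Fo / (fvfm + r$Fo / r$Fmp)
  }
  check_pair(fop, r$Fs, "Fo' <= Fs")
  if (any(r$Fmp - fop <= 0)) {
    stop("Fm' - Fo' must be positive at reading ", which(r$Fmp - fop <= 0)[1])
  }

  phiPSII <- (r$Fmp - r$Fs) / r$Fmp
  fvpfmp <- (r$Fmp - fop) / r$Fmp
  qP <- (r$Fmp - r$Fs) / (r$Fmp - fop)
  NPQ <- r$Fm / r$Fmp - 1
  ETR <- phiPSII * r$PPFD * config$psii_fraction * config$absorptance
  qe <- qe_partition(r, relaxed_Fmp = relaxed_Fmp)

  out <- data.frame(phiPSII = phiPSII, FvpFmp = fvpfmp, qP = qP, NPQ = NPQ,
                    ETR = ETR, qE = qe$qE, phiqE = qe$phiqE,
                    qE_ETR = qe$qE / ETR)
  if (!is.null(gas)) {
    g <- as.data.frame(gas, stringsAsFactors = FALSE)
    rd <- g$R_d %||% 0
    ag <- g$P_N + rd
    phiCO2 <- ag / (r$PPFD * config$absorptance)
    out$A_G <- ag
    out$phiCO2 <- phiCO2
    out$phiPSII_phiCO2 <- phiPSII / phiCO2
    out$ETR_AG <- ETR / ag
    out$P_N <- g$P_N
    out$g_s <- g$g_s
    out$E <- g$E
    out$C_i <- g$C_i
  }
  out
}

#' Partition non-photochemical quenching into its energy-dependent component
#'
#' Energy-dependent quenching (qE) is the rapidly relaxing, pH-driven part of
#' NPQ. Given the maximal fluorescence after relaxation of qE
#' (`relaxed_Fmp`, between `Fm'` and `Fm`), two expressions are returned that
#' differ in their assumption about PSII oxidation state:
#' `qE = Fm/Fm' - Fm/relaxed_Fm'` (all centres oxidised) and the quantum-yield
#' form `phiqE = Fs/Fm' - Fs/relaxed_Fm'`. Without a relaxation measurement
#' `relaxed_Fmp` defaults to `Fm`, attributing all NPQ to qE; the output is
#' flagged accordingly.
#'
#' @param reading Data frame/list with `Fs`, `Fmp`, `Fm`.
#' @param relaxed_Fmp Optional post-relaxation maximal fluorescence.
#' @return Data frame with columns `qE`, `phiqE` and logical
#'   `qE_assumed_all_npq`.
#' @export
qe_partition <- function(reading, relaxed_Fmp = NULL) {
  r <- as.data.frame(reading, stringsAsFactors = FALSE)
  assumed <- is.null(relaxed_Fmp)
  fr <- if (assumed) r$Fm else relaxed_Fmp
  if (any(fr < r$Fmp)) {
    stop("relaxed Fm' must be at least Fm' (reading ", which(fr < r$Fmp)[1], ")")
  }
  if (any(fr > r$Fm)) {
    stop("relaxed Fm' cannot exceed Fm (reading ", which(fr > r$Fm)[1], ")")
  }
  data.frame(qE = r$Fm / r$Fmp - r$Fm / fr,
             phiqE = r$Fs / r$Fmp - r$Fs / fr,
             qE_assumed_all_npq = rep(assumed, nrow(r)))
}

#' Total chlorophyll concentration from acetone-extract absorbances
#'
#' `(8.02 * A663 + 20.2 * A645) / DW` in mg per g dry weight, from absorbance
#' readings at 663 and 645 nm of an 80% acetone extract.
#'
#' @param A663,A645 Absorbances (non-negative).
#' @param DW Dry weight of the ground leaf material in g (positive).
#' @return Chlorophyll concentration, mg g^-1 DW.
#' @export
#' @examples
#' chlorophyll_concentration(0.5, 0.25, 0.1)
chlorophyll_concentration <- function(A663, A645, DW) {
  if (any(DW <= 0)) stop("dry weight must be positive")
  if (any(A663 < 0) || any(A645 < 0)) stop("absorbances must be non-negative")
  (8.02 * A663 + 20.2 * A645) / DW
}

#' Classify the memory pattern of a physiological parameter
#'
#' Applies the same two-position sign scheme as the gene classification:
#' the first sign is the direction of a significant S1 vs W difference
#' (two-sided t test at `alpha_phys` on per-plant values), the second sign
#' the direction of a significant S2 vs S1 difference; non-significant
#' contrasts give `=`. Welch's unequal-variance t is the default; set
#' `var_equal = TRUE` for the pooled-variance Student test.
#'
#' @param table A [physiology_table()].
#' @param parameter Parameter name to classify.
#' @param config A [run_config()] (supplies `alpha_phys`).
#' @param stages Stage labels `c(W, S1, S2)` used for the two contrasts.
#' @param var_equal Use pooled-variance t tests.
#' @return A one-row data frame of class `physiology_memory_call` with the
#'   signs, pattern, category and per-contrast t and p.
#' @export
classify_physiology_memory <- function(table, parameter,
                                       config = run_config(),
                                       stages = c("W", "S1", "S2"),
                                       var_equal = FALSE) {
  stopifnot(inherits(table, "physiology_table"), length(stages) == 3L)
  sub <- table[table$parameter == parameter, , drop = FALSE]
  if (!nrow(sub)) stop("parameter not present: ", parameter)
  values <- function(stage) {
    v <- sub$value[sub$stage == stage]
    if (length(v) < 2L) stop("need at least 2 plants at stage ", stage,
                             " for parameter ", parameter)
    v
  }
  w <- values(stages[1]); s1 <- values(stages[2]); s2 <- values(stages[3])
  t1 <- safe_t_test(w, s1, var_equal = var_equal)
  t2 <- safe_t_test(s1, s2, var_equal = var_equal)
  sig1 <- t1$p <= config$alpha_phys
  sig2 <- t2$p <= config$alpha_phys
  first <- if (sig1) (if (t1$mean_diff > 0) "+" else "-") else "="
  second <- if (sig2) (if (t2$mean_diff > 0) "+" else "-") else "="
  pattern <- make_pattern(first, second)
  out <- data.frame(parameter = parameter, first_sign = first,
                    second_sign = second, pattern = pattern,
                    category = pattern_category(pattern),
                    t_s1 = t1$t, p_s1 = t1$p, t_s2 = t2$t, p_s2 = t2$p,
                    stringsAsFactors = FALSE)
  class(out) <- c("physiology_memory_call", "data.frame")
  out
}

#' Classify all parameters of a physiology table
#'
#' @param table A [physiology_table()].
#' @inheritParams classify_physiology_memory
#' @return Data frame with one `physiology_memory_call` row per parameter.
#' @export
classify_physiology_table <- function(table, config = run_config(),
                                      stages = c("W", "S1", "S2"),
                                      var_equal = FALSE) {
  params <- unique(table$parameter)
  out <- do.call(rbind, lapply(params, function(p) {
    classify_physiology_memory(table, p, config, stages, var_equal)
  }))
  rownames(out) <- NULL
  out
}

#' Derive parameters for a raw-mode physiology table
#'
#' Converts a long physiology table holding raw fluorescence / gas-exchange
#' readings (parameters `Fs`, `Fmp`, `Fo`, `Fm`, optional `Fop`, `PPFD`,
#' `P_N`, `g_s`, `E`, `C_i`, optional `relaxed_Fmp`) into a table of derived
#' parameters per plant and stage; pass-through parameters (e.g. `RWC`,
#' `ABA`, `chlorophyll`) are retained unchanged.
#'
#' @param table A [physiology_table()] in raw mode.
#' @param config A [run_config()].
#' @return A derived-mode [physiology_table()].
#' @export
derive_physiology <- function(table, config = run_config()) {
  stopifnot(inherits(table, "physiology_table"))
  design <- attr(table, "design")
  wide <- stats::reshape(as.data.frame(table), direction = "wide",
                         idvar = c("plant_id", "stage"),
                         timevar = "parameter")
  names(wide) <- sub("^value\\.", "", names(wide))
  raw_fields <- c("Fs", "Fmp", "Fo", "Fm", "Fop", "PPFD",
                  "P_N", "g_s", "E", "C_i", "R_d", "relaxed_Fmp")
  if (!all(c("Fs", "Fmp", "Fo", "Fm", "PPFD") %in% names(wide))) {
    stop("raw-mode physiology table lacks fluorescence fields")
  }
  gas <- if ("P_N" %in% names(wide)) wide[intersect(c("P_N", "g_s", "E", "C_i", "R_d"),
                                                    names(wide))] else NULL
  relaxed <- if ("relaxed_Fmp" %in% names(wide)) wide$relaxed_Fmp else NULL
  derived <- derive_fluorescence(wide[intersect(c("Fs", "Fmp", "Fo", "Fm", "Fop", "PPFD"),
                                                names(wide))],
                                 gas = gas, config = config,
                                 relaxed_Fmp = relaxed)
  derived$qE_assumed_all_npq <- NULL
  passthrough <- setdiff(names(wide), c("plant_id", "stage", raw_fields))
  keep <- cbind(wide[c("plant_id", "stage")], derived,
                wide[passthrough])
  long <- stats::reshape(keep, direction = "long",
                         varying = setdiff(names(keep), c("plant_id", "stage")),
                         v.names = "value", timevar = "parameter",
                         times = setdiff(names(keep), c("plant_id", "stage")),
                         idvar = c("plant_id", "stage"))
  rownames(long) <- NULL
  physiology_table(long[c("plant_id", "stage", "parameter", "value")], design)
}
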