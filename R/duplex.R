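## Two-state DNA duplex thermodynamics: unified nearest-neighbor parameters
## (SantaLucia unified set; dH in kcal/mol, dS in cal/mol/K, 1 M NaCl
## reference) with the Owczarzy 2008 Mg2+/monovalent melting correction.

.NN_DH <- c("AA" = -7.9, "TT" = -7.9, "AT" = -7.2, "TA" = -7.2,
            "CA" = -8.5, "TG" = -8.5, "GT" = -8.4, "AC" = -8.4,
            "CT" = -7.8, "AG" = -7.8, "GA" = -8.2, "TC" = -8.2,
            "CG" = -10.6, "GC" = -9.8, "GG" = -8.0, "CC" = -8.0)
.NN_DS <- c("AA" = -22.2, "TT" = -22.2, "AT" = -20.4, "TA" = -21.3,
            "CA" = -22.7, "TG" = -22.7, "GT" = -22.4, "AC" = -22.4,
            "CT" = -21.0, "AG" = -21.0, "GA" = -22.2, "TC" = -22.2,
            "CG" = -27.2, "GC" = -24.4, "GG" = -19.9, "CC" = -19.9)
.INIT_AT <- c(dH = 2.3, dS = 4.1)
.INIT_GC <- c(dH = 0.1, dS = -2.8)
.SYM_DS <- -1.4

#' Nearest-neighbor duplex thermodynamics of a DNA sequence
#'
#' Sums the unified nearest-neighbor stack enthalpies/entropies plus terminal
#' initiation terms, with the symmetry correction for self-complementary
#' sequences. Reference state: 1 M NaCl.
#'
#' @param sequence DNA sequence, 5'->3', A/C/G/T only, length >= 2. The
#'   perfect-complement duplex is assumed.
#' @return A `duplex_thermo`: `sequence`, `dH` (kcal/mol), `dS` (cal/mol/K),
#'   `self_complementary`, `gc_fraction`, `n_bp`.
#' @export
#' @examples
#' th <- nn_thermo(oligo_sequences[["fret24_1"]])
#' c(th$dH, th$dS)
nn_thermo <- function(sequence) {
  s <- toupper(gsub("\\s", "", sequence))
  if (nchar(s) < 2L) stop("nn_thermo: sequence must have length >= 2",
                          call. = FALSE)
  chars <- strsplit(s, "")[[1]]
  if (!all(chars %in% c("A", "C", "G", "T"))) {
    stop("nn_thermo: sequence must contain only A/C/G/T", call. = FALSE)
  }
  stacks <- paste0(chars[-length(chars)], chars[-1])
  dH <- sum(.NN_DH[stacks])
  dS <- sum(.NN_DS[stacks])
  for (end in c(chars[1], chars[length(chars)])) {
    term <- if (end %in% c("A", "T")) .INIT_AT else .INIT_GC
    dH <- dH + term[["dH"]]
    dS <- dS + term[["dS"]]
  }
  selfc <- identical(s, reverse_complement(s))
  if (selfc) dS <- dS + .SYM_DS
  structure(list(sequence = s, dH = dH, dS = dS, self_complementary = selfc,
                 gc_fraction = mean(chars %in% c("G", "C")),
                 n_bp = nchar(s)),
            class = "duplex_thermo")
}

#' @export
print.duplex_thermo <- function(x, ...) {
  cat(sprintf("<duplex_thermo> %d bp%s  dH = %.1f kcal/mol, dS = %.1f cal/mol/K\n",
              x$n_bp, if (x$self_complementary) " (self-complementary)" else "",
              x$dH, x$dS))
  invisible(x)
}

#' Ionic and strand-concentration context for duplex equilibria
#'
#' @param na,k Sodium/potassium, mM.
#' @param tris Tris buffer concentration, mM; its effective monovalent-cation
#'   contribution is `tris_factor * tris` (default half, the protonated
#'   fraction at pH ~7, exposed because the buffer's effective contribution
#'   is an empirical convention).
#' @param mg Magnesium, mM.
#' @param ct Total strand concentration, M.
#' @param temperature degC.
#' @param tris_factor Fraction of Tris counted as monovalent cation.
#' @return An `ion_conditions` list with the derived `monovalent` (mM).
#' @export
#' @examples
#' # the loaded FRET buffer: 10 mM Tris pH 7, 50 uM MgCl2, 3.9 mM NaCl
#' fret_buffer_ions()
ion_conditions <- function(na = 0, k = 0, tris = 0, mg = 0, ct = 1e-6,
                           temperature = 45, tris_factor = 0.5) {
  if (any(c(na, k, tris, mg) < 0) || ct <= 0) {
    stop("ion_conditions: concentrations must be non-negative, ct positive",
         call. = FALSE)
  }
  mono <- na + k + tris_factor * tris
  if (mono < 0.1) {
    warning("monovalent below 0.1 mM: outside the validated range of the salt
correction")
  }
  structure(list(na = na, k = k, tris = tris, mg = mg,
                 monovalent = mono, ct = ct,
                 temperature = temperature, tris_factor = tris_factor),
            class = "ion_conditions")
}

#' @rdname ion_conditions
#' @param ... Overrides passed to [ion_conditions()].
#' @export
fret_buffer_ions <- function(...) {
  args <- modifyList(list(na = 3.9, tris = 10, mg = 0.05, ct = 10e-6,
                          temperature = 45), list(...))
  do.call(ion_conditions, args)
}

## Owczarzy et al. 2008 reciprocal-Tm salt correction (1/K). Decision tree on
## R = sqrt([Mg2+]) / [monovalent]: monovalent-dominated below 0.22,
## Mg-dominated above 6, mixed in between (a, d, g become functions of the
## monovalent concentration).
owczarzy_correction <- function(gc_fraction, n_bp, monovalent_mM, mg_mM) {
  mon <- monovalent_mM * 1e-3
  mg <- mg_mM * 1e-3
  a <- 3.92; b <- -0.911; cc <- 6.26; d <- 1.42
  e <- -48.2; f <- 52.5; g <- 8.31
  if (mon > 0) {
    R <- sqrt(mg) / mon
    if (R < 0.22) {
      return((4.29 * gc_fraction - 3.95) * 1e-5 * log(mon) +
               9.40e-6 * log(mon)^2)
    }
    if (R < 6.0) {
      a <- 3.92 * (0.843 - 0.352 * sqrt(mon) * log(mon))
      d <- 1.42 * (1.279 - 4.03e-3 * log(mon) - 8.03e-3 * log(mon)^2)
      g <- 8.31 * (0.486 - 0.258 * log(mon) + 5.25e-3 * log(mon)^3)
    }
  }
  (a + b * log(mg) + gc_fraction * (cc + d * log(mg)) +
      (1 / (2 * (n_bp - 1))) * (e + f * log(mg) + g * log(mg)^2)) * 1e-5
}

#' Two-state melting temperature under given ionic conditions
#'
#' `Tm = dH / (dS + R ln(CT/x))` at the 1 M NaCl reference (`x = 4` for
#' non-self-complementary duplexes, 1 otherwise), then corrected to the given
#' monovalent/Mg2+ conditions with the Owczarzy 2008 reciprocal-Tm formula.
#' Tm rises monotonically with Mg2+ and along the joint salt-accumulation
#' direction of the chamber (all cations scaled together).
#'
#' @param thermo A [nn_thermo()] result.
#' @param ions An [ion_conditions()].
#' @return Melting temperature in degC, with attribute `"flagged"` if the
#'   conditions are outside the correction's validated range (monovalent
#'   below 0.1 mM).
#' @export
melting_temperature <- function(thermo, ions) {
  stopifnot(inherits(thermo, "duplex_thermo"), inherits(ions, "ion_conditions"))
  x <- if (thermo$self_complementary) 1 else 4
  tm_ref <- thermo$dH * 1000 / (thermo$dS + .R_CAL * log(ions$ct / x))
  flagged <- FALSE
  if (ions$mg > 0 || ions$monovalent < 1000) {
    if (ions$mg <= 0) {
      corr <- owczarzy_correction(thermo$gc_fraction, thermo$n_bp,
                                  ions$monovalent, 1e-12)
      # pure-monovalent branch is reached with vanishing Mg via R < 0.22
    } else {
      corr <- owczarzy_correction(thermo$gc_fraction, thermo$n_bp,
                                  ions$monovalent, ions$mg)
    }
    tm <- 1 / (1 / tm_ref + corr)
  } else {
    tm <- tm_ref
  }
  if (ions$monovalent < 0.1) flagged <- TRUE
  structure(tm - 273.15, flagged = flagged)
}

#' Equilibrium duplex fraction at given temperature and ions
#'
#' Two-state (all-or-none) hybridization: the fraction of strands in duplex
#' form at the `ion_conditions` temperature and total strand concentration.
#' The salt correction enters as an effective entropy consistent with the
#' corrected Tm, so `f = 0.5` exactly at `T = Tm`.
#'
#' @inheritParams melting_temperature
#' @return Duplex fraction in `[0, 1]`.
#' @export
duplex_fraction <- function(thermo, ions) {
  stopifnot(inherits(thermo, "duplex_thermo"), inherits(ions, "ion_conditions"))
  x <- if (thermo$self_complementary) 1 else 4
  tm_K <- as.numeric(melting_temperature(thermo, ions)) + 273.15
  # entropy implied by the corrected Tm at this CT
  dS_eff <- thermo$dH * 1000 / tm_K - .R_CAL * log(ions$ct / x)
  TK <- ions$temperature + 273.15
  dG <- thermo$dH * 1000 - TK * dS_eff
  K <- exp(-dG / (.R_CAL * TK))
  # 2f / ((1-f)^2 CT) = K  (non-self-compl.);  f / (2 (1-f)^2 CT) = K (self)
  a <- if (thermo$self_complementary) 2 * K * ions$ct else K * ions$ct / 2
  if (!is.finite(a) || a > 1e14) return(1)
  if (a <= 0) return(0)
  f <- (2 * a + 1 - sqrt((2 * a + 1)^2 - 4 * a^2)) / (2 * a)
  min(max(f, 0), 1)
}

#' Strand-state timeline and separation-cycle count along a trajectory
#'
#' Computes the two-state duplex fraction pointwise from aligned time series
#' of ion and strand concentrations, then counts melt/anneal events with
#' hysteresis: the duplex counts as melted once `f < melt_f` and as re-annealed
#' once `f > anneal_f`; one full cycle is a melt followed by an anneal.
#'
#' @param thermo A [nn_thermo()] result.
#' @param times Time stamps, s.
#' @param mg Mg2+ series, mM.
#' @param ct Total strand concentration series, M.
#' @param monovalent Monovalent cation series, mM (scalar recycled).
#' @param temperature degC (scalar).
#' @param melt_f,anneal_f Hysteresis thresholds on the duplex fraction.
#' @return A `strand_timeline`: data.frame (`time`, `f`, `state`) plus
#'   `n_cycles`.
#' @export
separation_cycles <- function(thermo, times, mg, ct, monovalent = 3.9,
                              temperature = 45,
                              melt_f = 0.1, anneal_f = 0.9) {
  n <- length(times)
  if (length(mg) != n || length(ct) != n) {
    stop("separation_cycles: times, mg and ct must be aligned", call. = FALSE)
  }
  monovalent <- rep_len(monovalent, n)
  f <- vapply(seq_len(n), function(i) {
    ions <- ion_conditions(na = monovalent[i], mg = mg[i],
                           ct = max(ct[i], 1e-12),
                           temperature = temperature, tris_factor = 0)
    duplex_fraction(thermo, ions)
  }, numeric(1))
  state <- character(n)
  cur <- if (f[1] > 0.5) "annealed" else "melted"
  n_cycles <- 0L
  melted_since_anneal <- FALSE
  for (i in seq_len(n)) {
    if (cur == "annealed" && f[i] < melt_f) {
      cur <- "melted"
      melted_since_anneal <- TRUE
    } else if (cur == "melted" && f[i] > anneal_f) {
      cur <- "annealed"
      if (melted_since_anneal) n_cycles <- n_cycles + 1L
    }
    state[i] <- cur
  }
  structure(list(timeline = data.frame(time = times, f = f, state = state),
                 n_cycles = n_cycles, melt_f = melt_f, anneal_f = anneal_f),
            class = "strand_timeline")
}

#' @export
print.strand_timeline <- function(x, ...) {
  cat(sprintf("<strand_timeline> %d point(s), %d separation cycle(s)\n",
              nrow(x$timeline), x$n_cycles))
  invisible(x)
}

#' Duplex-fraction map over the chamber
#'
#' Combines the steady salt and DNA concentration fields into a spatial map
#' of the two-state duplex fraction at chamber temperature: the model-side
#' analogue of a FRET micrograph (high f = duplex/high FRET at the vortex,
#' low f = separated strands in the pure upflow).
#'
#' @param mg_field `concentration_field` of Mg2+ (relative to the load).
#' @param dna_field `concentration_field` of the strand (relative), or `NULL`
#'   to hold strand concentration fixed at the loaded value.
#' @param thermo A [nn_thermo()] result.
#' @param ions Loaded-buffer [ion_conditions()] (e.g. [fret_buffer_ions()]).
#' @param include_ct Scale the local total strand concentration by the DNA
#'   field (set `FALSE` to isolate the salt effect).
#' @return Matrix (nx x ny) of duplex fractions.
#' @export
duplex_fraction_map <- function(mg_field, dna_field, thermo, ions,
                                include_ct = TRUE) {
  stopifnot(inherits(mg_field, "concentration_field"))
  mg_r <- mg_field$c[, , dim(mg_field$c)[3]]
  ct_r <- if (include_ct && !is.null(dna_field)) {
    dna_field$c[, , dim(dna_field$c)[3]]
  } else matrix(1, nrow(mg_r), ncol(mg_r))
  fmap <- matrix(0, nrow(mg_r), ncol(mg_r))
  for (i in seq_len(nrow(mg_r))) {
    for (j in seq_len(ncol(mg_r))) {
      loc <- ion_conditions(na = ions$na, k = ions$k, tris = ions$tris,
                            mg = max(ions$mg * mg_r[i, j], 1e-9),
                            ct = max(ions$ct * ct_r[i, j], 1e-15),
                            temperature = ions$temperature,
                            tris_factor = ions$tris_factor)
      fmap[i, j] <- duplex_fraction(thermo, loc)
    }
  }
  fmap
}
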