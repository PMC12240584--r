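## Frozen oracle values computed with an independent nearest-neighbor
## calculator (Biopython MeltingTemp, unified NN table, Owczarzy 2008 Mg
## correction) for the study's 24mer FRET strand at 10 uM total strands:
##   dH = -183.1 kcal/mol, dS = -510.4 cal/mol/K
##   Tm(1 M Na+)                          = 68.43 degC
##   Tm(3.9 mM Na+, 10 mM Tris, 50 uM Mg) = 48.82 degC
##   Tm(9x accumulated salt)              = 55.75 degC

fret24 <- oligo_sequences[["fret24_1"]]

test_that("nearest-neighbor sums match the independent calculator", {
  th <- nn_thermo(fret24)
  expect_equal(th$dH, -183.1, tolerance = 1e-6)
  expect_equal(th$dS, -510.4, tolerance = 1e-6)
  expect_false(th$self_complementary)
  # reverse complement pairs the same duplex
  th_rc <- nn_thermo(reverse_complement(fret24))
  expect_equal(th_rc$dH, th$dH)
  expect_equal(th_rc$dS, th$dS)
})

test_that("self-complementary sequences get the symmetry correction", {
  th_sym <- nn_thermo("GCATATGC")       # its own reverse complement
  th_asym <- nn_thermo("GCATATGG")
  expect_true(th_sym$self_complementary)
  expect_false(th_asym$self_complementary)
  # symmetry term only affects entropy
  parts <- nn_thermo("GCATATGC")
  expect_equal(parts$dS,
               sum(evapopore:::.NN_DS[c("GC", "CA", "AT", "TA", "AT", "TG",
                                        "GC")]) +
                 2 * evapopore:::.INIT_GC[["dS"]] + evapopore:::.SYM_DS,
               tolerance = 1e-9)
})

test_that("sequence validation rejects non-ACGT and too-short input", {
  expect_error(nn_thermo("ACGTN"), "A/C/G/T")
  expect_error(nn_thermo("A"), "length >= 2")
})

test_that("melting temperatures match the independent oracle within 0.5 degC", {
  th <- nn_thermo(fret24)
  tm_1M <- melting_temperature(th, ion_conditions(na = 1000, ct = 10e-6))
  expect_equal(as.numeric(tm_1M), 68.43, tolerance = 0.5 / 68)
  tm_buf <- melting_temperature(th, fret_buffer_ions())
  expect_equal(as.numeric(tm_buf), 48.82, tolerance = 0.5 / 49)
  tm_9x <- melting_temperature(th, fret_buffer_ions(na = 3.9 * 9,
                                                    mg = 0.05 * 9))
  expect_equal(as.numeric(tm_9x), 55.75, tolerance = 0.5 / 56)
})

test_that("loaded buffer leaves the diluted 24mer single-stranded at 45 degC,
           ninefold salt anneals it", {
  th <- nn_thermo(fret24)
  # in the upflow the strands are diluted along with the salt; at the loaded
  # concentration itself the duplex sits near its melting point
  dilute <- fret_buffer_ions(ct = 1e-7)
  expect_lt(as.numeric(melting_temperature(th, dilute)), 45)
  expect_lt(duplex_fraction(th, dilute), 0.5)
  strong <- fret_buffer_ions(na = 3.9 * 9, mg = 0.05 * 9)
  expect_gt(as.numeric(melting_temperature(th, strong)), 45)
  expect_gt(duplex_fraction(th, strong), 0.5)
})

test_that("Tm is monotone in Mg and along salt accumulation", {
  th <- nn_thermo(fret24)
  tms_mg <- vapply(c(0.05, 0.15, 0.45), function(mg)
    as.numeric(melting_temperature(th, fret_buffer_ions(mg = mg))),
    numeric(1))
  expect_true(all(diff(tms_mg) > 0))
  # interfacial accumulation scales Na+ and Mg2+ together; Tm rises along
  # that direction (monovalent alone at trace Mg competes with Mg binding
  # and need not be monotone)
  tms_acc <- vapply(c(1, 3, 9), function(k)
    as.numeric(melting_temperature(th, fret_buffer_ions(na = 3.9 * k,
                                                        mg = 0.05 * k))),
    numeric(1))
  expect_true(all(diff(tms_acc) > 0))
})

test_that("two-state identity: Tm slope in ln(CT) set by dH", {
  th <- nn_thermo(fret24)
  cts <- c(1e-7, 1e-6, 1e-5)
  tms <- vapply(cts, function(ct) as.numeric(melting_temperature(
    th, ion_conditions(na = 1000, ct = ct))) + 273.15, numeric(1))
  # 1/Tm = (dS + R ln(CT/4)) / dH  =>  d(1/Tm)/d ln CT = R / dH
  slopes <- diff(1 / tms) / diff(log(cts))
  expect_equal(slopes, rep(1.9872 / (th$dH * 1000), 2), tolerance = 1e-6)
})

test_that("duplex fraction is half at Tm, one when cold, zero when hot", {
  th <- nn_thermo(fret24)
  ions <- fret_buffer_ions()
  tm <- as.numeric(melting_temperature(th, ions))
  at <- function(T) duplex_fraction(th, fret_buffer_ions(temperature = T))
  expect_equal(at(tm), 0.5, tolerance = 1e-9)
  expect_gt(at(0), 0.99)
  expect_lt(at(tm + 40), 0.01)
  # continuous and strictly decreasing in temperature
  ts <- seq(tm - 20, tm + 20, by = 2)
  fs <- vapply(ts, at, numeric(1))
  expect_true(all(diff(fs) < 0))
})

test_that("separation cycles are counted with hysteresis on constructed salt
           series", {
  th <- nn_thermo(fret24)
  ions <- fret_buffer_ions()
  # square wave between the loaded buffer (melted when diluted) and 9x salt
  n_rep <- 6
  seg <- 25
  mg_hi <- 0.45; mg_lo <- 0.005
  mg <- rep(rep(c(mg_hi, mg_lo), each = seg), n_rep)
  ct <- rep(rep(c(1e-5, 1e-8), each = seg), n_rep)
  times <- seq_along(mg)
  tl <- separation_cycles(th, times, mg, ct, monovalent = 35,
                          temperature = 45)
  # each low-salt excursion melts, each return anneals: n_rep - ends
  expect_gte(tl$n_cycles, n_rep - 1)
  expect_lte(tl$n_cycles, n_rep)
  expect_true(all(tl$timeline$f >= 0 & tl$timeline$f <= 1))
  # constant high salt: always annealed, no cycles
  tl0 <- separation_cycles(th, times, rep(mg_hi, length(times)),
                           rep(1e-5, length(times)), monovalent = 35,
                           temperature = 45)
  expect_equal(tl0$n_cycles, 0)
  expect_true(all(tl0$timeline$state == "annealed"))
  expect_error(separation_cycles(th, times, mg[-1], ct), "aligned")
})

test_that("duplex map separates the upflow from the vortex region", {
  fx <- small_flow()
  mg_field <- small_mg_steady()
  th <- nn_thermo(fret24)
  # strand concentration held at the loaded value: the salt field alone
  # already separates the two regions
  fmap <- duplex_fraction_map(mg_field, NULL, th, fret_buffer_ions())
  g <- fx$grid
  # low duplex fraction where the pure upflow enters
  expect_lt(mean(fmap[, 1:10]), 0.05)
  # high near the enriched interface, and the high-f centroid sits inside
  # the vortex region (upper chamber)
  expect_gt(max(fmap), 0.5)
  w <- fmap / sum(fmap)
  y_cent <- sum(t(w) * g$yc)
  expect_gt(y_cent, 0.6 * g$height)
})
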