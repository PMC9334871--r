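mkScatterTable <- function(h, w, a = h, fl = rep(10, length(h)),
                           via = rep(10, length(h))) {
    EventTable(cbind(`FSC-A` = a, `FSC-H` = h, `FSC-Width` = w,
                     `SSC-A` = rep(50, length(h)), FL1 = fl, VIA = via),
               flowAbVal:::SYNTH_CHANNELS)
}

test_that("basic gate geometries behave as closed regions", {
    tab <- mkScatterTable(h = c(10, 50, 100), w = c(10, 60, 90))
    all_pass <- GateSpec("all", "rectangle", c("FSC-H", "FSC-Width"),
                         xlim = c(0, Inf), ylim = c(0, Inf))
    expect_true(all(applyGate(tab, all_pass)))

    # boundary events are included
    box <- GateSpec("box", "rectangle", c("FSC-H", "FSC-Width"),
                    xlim = c(50, 100), ylim = c(60, 90))
    expect_equal(applyGate(tab, box), c(FALSE, TRUE, TRUE))

    thr_inf <- GateSpec("t", "threshold", "VIA", value = Inf)
    expect_true(all(applyGate(tab, thr_inf)))
    thr0 <- GateSpec("t0", "threshold", "VIA", value = 0)
    expect_false(any(applyGate(tab, thr0)))
})

test_that("polygon gates use the even-odd rule with inclusive boundary", {
    tri <- rbind(c(0, 0), c(100, 0), c(0, 100))
    gate <- GateSpec("tri", "polygon", c("FSC-H", "FSC-Width"),
                     vertices = tri)
    tab <- mkScatterTable(h = c(10, 90, 50, 0, 60),
                          w = c(10, 90, 50, 0, 0))
    # interior, exterior, boundary (hypotenuse), vertex, edge
    expect_equal(applyGate(tab, gate), c(TRUE, FALSE, TRUE, TRUE, TRUE))
    expect_error(GateSpec("bad", "polygon", c("FSC-H", "FSC-Width"),
                          vertices = rbind(c(0, 0), c(1, 1), c(2, 2))),
                 "collinear")
})

test_that("viability gating excludes the dye-positive fraction", {
    tab <- mkScatterTable(h = rep(100, 4), w = rep(60, 4),
                          via = c(10, 20, 30, 40))
    expect_true(all(gateViability(tab, threshold = 50)))
    expect_false(any(gateViability(tab, threshold = 0)))

    s <- generateSample(syntheticSampleSpec(500), seed = 21)
    # dead dye geometric mean is 20x the live background
    kept <- gateViability(s$table, threshold = 300)
    expect_equal(mean(!kept), 0.10, tolerance = 0.01 / 0.10)
    dead <- s$truth$labels == "dead"
    expect_gt(mean(!kept[dead]), 0.999)
})

test_that("singlet gating keeps constant-ratio events and drops doublets", {
    h <- c(100, 200, 50)
    tab <- mkScatterTable(h = h, a = 1.1 * h, w = rep(60, 3))
    expect_true(all(gateSinglets(tab)))          # normalized ratio = 1
    expect_true(all(gateSinglets(tab, normalize = FALSE,
                                 r_lo = 1.05, r_hi = 1.15)))

    # zero-height events are excluded and counted
    tab0 <- mkScatterTable(h = c(100, 0), a = c(100, 5), w = c(60, 60))
    mask <- gateSinglets(tab0)
    expect_equal(attr(mask, "zero_height"), 1L)
    expect_false(mask[2])

    s <- generateSample(syntheticSampleSpec(500), seed = 8)
    mask <- gateSinglets(s$table)
    doublet <- s$truth$labels == "doublet"
    expect_gt(mean(!mask[doublet]), 0.99)

    # an empty band on continuous data keeps essentially nothing
    tiny <- gateSinglets(s$table, r_lo = 1, r_hi = 1)
    expect_lt(mean(tiny), 0.001)
})

test_that("hierarchies are conjunctive, monotone and idempotent", {
    s <- generateSample(syntheticSampleSpec(700), seed = 3)
    all_pass <- GateHierarchy(list(
        GateSpec("a", "rectangle", c("FSC-H", "FSC-Width"),
                 xlim = c(0, Inf), ylim = c(0, Inf)),
        GateSpec("b", "threshold", "VIA", value = Inf)))
    pop <- applyHierarchy(s$table, all_pass)
    expect_equal(sum(pop@finalMask), nEvents(s$table))

    h <- defaultHierarchy("scatter_only")
    pop <- applyHierarchy(s$table, h)
    expect_true(all(diff(pop@counts) <= 0))
    expect_equal(pop@finalMask,
                 Reduce(`&`, lapply(h@gates, applyGate, table = s$table)))
    # idempotence: gating the gated table changes nothing
    sub <- subsetEvents(s$table, pop)
    again <- applyGate(sub, h@gates[[1]])
    expect_true(all(again))
})

test_that("gating recovers the ground-truth live singlets", {
    s <- generateSample(syntheticSampleSpec(1000), seed = 11)
    pop <- applyHierarchy(s$table, defaultHierarchy("scatter_only"))
    live <- s$truth$labels == "live_singlet"
    expect_gt(mean(pop@finalMask[live]), 0.99)          # recovery
    expect_gt(mean(!pop@finalMask[s$truth$labels == "debris"]), 0.99)
    expect_gt(mean(live[pop@finalMask]), 0.99)          # purity
})

test_that("the two gating strategies agree and recover the true mean", {
    s <- generateSample(syntheticSampleSpec(1000, 0.5), seed = 17)
    n1 <- sum(applyHierarchy(s$table,
                             defaultHierarchy("scatter_only"))@finalMask)
    n2 <- sum(applyHierarchy(s$table,
                             defaultHierarchy("viability_dye"))@finalMask)
    expect_lt(abs(n1 - n2) / n1, 0.02)

    pop <- applyHierarchy(s$table, defaultHierarchy("scatter_only"))
    mfi <- populationStats(subsetEvents(s$table, pop), "FL1")[["MFI"]]
    expect_equal(mfi, s$truth$live_fl_mean,
                 tolerance = 0.02)
})

test_that("a debris-only sample is fully excluded", {
    spec <- syntheticSampleSpec(500, fractions = c(live_singlet = 0,
                                                   debris = 1, dead = 0,
                                                   doublet = 0))
    s <- generateSample(spec, seed = 5)
    pop <- applyHierarchy(s$table, defaultHierarchy("scatter_only"))
    expect_equal(sum(pop@finalMask), 0L)
})

test_that("event-count QC applies the 20,000-event floor", {
    s <- generateSample(syntheticSampleSpec(500, n_events = 20000L), 1)
    pop <- applyHierarchy(s$table, defaultHierarchy("scatter_only"))
    expect_true(qcMinEvents(pop)$pass)
    s2 <- generateSample(syntheticSampleSpec(500, n_events = 19999L), 1)
    expect_false(qcMinEvents(applyHierarchy(
        s2$table, defaultHierarchy("scatter_only")))$pass)
    expect_false(qcMinEvents(s2$table, minimum = 20000L)$pass)
})
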