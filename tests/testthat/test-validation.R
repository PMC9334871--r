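# The three published titration tables (stain index by amount) and
# blocking panels, used as printed inputs to the decision layer.
paperTitrations <- function() {
    list(`2A7` = list(stats = data.frame(amount = c(1, 2, 5),
                                         si = c(10.3, 15.53, 19.51)),
                      reference = 1),
         LB509 = list(stats = data.frame(amount = c(0.2, 0.5, 1),
                                         si = c(4.89, 5.28, 7.37)),
                      reference = 1),
         MJFR1 = list(stats = data.frame(amount = c(0.1, 0.5, 1, 5),
                                         si = c(7.52, 4.05, 4.19, 0.83)),
                      reference = 0.1))
}

paperBlockingPanels <- function() {
    list(`2A7` = data.frame(
             blocker = c("aSyn_monomer", "aSyn_monomer", "bSyn", "gSyn",
                         "tubulin", "tubulin"),
             condition = c("600x_RT", "300x_37C", "600x_RT", "600x_RT",
                           "600x_RT_HEK", "600x_RT_hiPSC"),
             efficiency = c(0.87, 0.98, 0.49, 0.15, 0.07, 0.19)),
         MJFR1 = data.frame(
             blocker = c("aSyn_monomer", "aSyn_monomer", "bSyn", "gSyn",
                         "tubulin", "tubulin"),
             condition = c("600x_RT", "300x_37C", "600x_RT", "600x_RT",
                           "600x_RT_HEK", "600x_RT_hiPSC"),
             efficiency = c(0.96, 0.94, 0.87, 0.43, 0.26, 0.05)),
         LB509 = data.frame(
             blocker = c("aSyn_monomer", "aSyn_monomer"),
             condition = c("600x_RT", "300x_37C"),
             efficiency = c(0.49, 0.56)))
}

test_that("titration evaluation reports SI and fold changes", {
    st <- data.frame(amount = c(1, 2), mfi_ab = c(500, 500),
                     mfi_iso = c(50, 50), sd_iso = c(10, 10))
    tab <- evaluateTitration(titrationSeries("x", st, reference = 1))
    expect_equal(tab$ratio_mfi_ab, c(1, 1))
    expect_equal(tab$ratio_mfi_iso, c(1, 1))
    expect_equal(tab$si, c(22.5, 22.5))

    expect_error(evaluateTitration(titrationSeries(
        "x", st[1, ], reference = 1)), "2 amounts")
    expect_error(titrationSeries("x", st, reference = 3), "reference")
})

test_that("synthetic saturation series: SI saturates, isotype grows linearly", {
    model <- bindingModel(Bmax = 1000, Kd = 1, slope = 30,
                          background = 100, cv = 0.5)
    gen <- generateTitrationSeries(model, c(0.5, 1, 2, 5), seed = 7,
                                   n_events = 5000L)
    tr <- gen$truth
    # true SI rises initially, then flattens/declines as specific binding
    # saturates against the linearly growing isotype background
    expect_gt(tr$si_true[2], tr$si_true[1])
    rel_gain <- diff(tr$si_true) / tr$si_true[-nrow(tr)]
    expect_true(all(diff(rel_gain) < 0))
    # measured isotype ratio MFI grows linearly in amount
    stats <- do.call(rbind, lapply(gen$pairs, measureStainPair))
    tab <- evaluateTitration(titrationSeries("ab", stats, reference = 1))
    iso_true <- (model$background + model$slope * tab$amount) /
        (model$background + model$slope * 1)
    expect_equal(tab$ratio_mfi_iso, iso_true, tolerance = 0.05)
})

test_that("the titration policy reproduces all three published choices", {
    pt <- paperTitrations()
    picks <- vapply(pt, function(p)
        selectOptimalAmount(titrationSeries("ab", p$stats, p$reference),
                            theta = 0.75), numeric(1))
    expect_equal(unname(picks), c(2, 1, 0.1))
})

test_that("the titration policy has the right limiting behaviour", {
    st <- data.frame(amount = c(0.5, 1, 2, 5), si = c(3, 8, 11, 12))
    series <- titrationSeries("ab", st, reference = 1)
    expect_equal(selectOptimalAmount(series, theta = 1), 5)
    expect_equal(selectOptimalAmount(series, theta = 1e-9), 0.5)
    # infeasible isotype cap falls back to the max-SI amount, with warning
    tab <- data.frame(amount = st$amount, si = st$si,
                      ratio_mfi_iso = c(2, 3, 4, 5))
    expect_warning(pick <- selectOptimalAmount(tab, iso_ratio_cap = 1),
                   "max-SI")
    expect_equal(pick, 5)
})

test_that("blocking panels aggregate replicates and reject duplicates", {
    single <- data.frame(blocker = "aSyn_monomer", efficiency = 0.9)
    prof <- summarizeBlockingPanel(single, "ab")
    expect_equal(prof$summary$mean_efficiency, 0.9)

    reps <- data.frame(blocker = "aSyn_monomer", replicate = c(1, 2),
                       efficiency = c(0.86, 0.88))
    expect_equal(summarizeBlockingPanel(reps, "ab")$summary$mean_efficiency,
                 0.87)

    empty <- summarizeBlockingPanel(data.frame(), "ab")
    expect_equal(nrow(empty$summary), 0L)

    dup <- data.frame(blocker = c("bSyn", "bSyn"), efficiency = c(0.5, 0.6))
    expect_error(summarizeBlockingPanel(dup, "ab"), "duplicate")
})

test_that("specificity classification matches the published panels", {
    panels <- paperBlockingPanels()
    cls <- lapply(names(panels), function(ab)
        classifySpecificity(summarizeBlockingPanel(panels[[ab]], ab)))
    names(cls) <- names(panels)
    expect_true(cls$`2A7`$specific)
    expect_equal(cls$`2A7`$cross_reactive_with, "bSyn")
    expect_true(cls$MJFR1$specific)
    expect_setequal(cls$MJFR1$cross_reactive_with, c("bSyn", "gSyn"))
    expect_false(cls$LB509$specific)

    no_self <- summarizeBlockingPanel(
        data.frame(blocker = "bSyn", efficiency = 0.5), "ab")
    expect_error(classifySpecificity(no_self), "self-blocker")
})

test_that("expression classes use the floor and detection threshold", {
    si_2a7 <- c(HEK = 20.38, hiPSC = 17.32, T_cell = 4.46,
                fibroblast = 1.70)
    res <- classifyExpression(si_2a7)
    expect_true(all(res$classes == "detected"))
    expect_equal(res$ordering,
                 c("HEK", "hiPSC", "T_cell", "fibroblast"))

    res2 <- classifyExpression(c(T_cell = 1.36, fibroblast = NA))
    expect_equal(unname(res2$classes), c("marginal", "not_detected"))
})

test_that("antibody ranking reproduces the published order and is stable", {
    panels <- paperBlockingPanels()
    cls <- lapply(names(panels), function(ab)
        classifySpecificity(summarizeBlockingPanel(panels[[ab]], ab)))
    ranked <- rankAntibodies(cls)
    expect_equal(ranked$antibody, c("2A7", "MJFR1", "LB509"))

    # permutation invariance
    ranked2 <- rankAntibodies(cls[c(3, 1, 2)])
    expect_equal(ranked2$antibody, ranked$antibody)

    # single antibody and exact ties keep input order
    expect_equal(rankAntibodies(cls[2])$antibody, "MJFR1")
    twin <- list(cls[[1]], cls[[1]])
    twin[[2]]$antibody <- "copy"
    expect_equal(rankAntibodies(twin)$antibody, c("2A7", "copy"))
})
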