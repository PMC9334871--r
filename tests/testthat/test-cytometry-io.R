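test_that("CSV round trip is lossless and errors are located", {
    m <- cbind(`FSC-A` = c(100.25, 2.5, 3), `FL1` = c(0.125, 7e5, 1 / 3))
    tab <- EventTable(m, c(`FSC-A` = "FSC-A", FL1 = "fluorescence"),
                      meta = list(condition = "stained"))
    path <- withr::local_tempfile(fileext = ".csv")
    writeEventCSV(tab, path)
    back <- readEventCSV(path)
    expect_identical(eventMatrix(back), eventMatrix(tab))
    expect_identical(channelDefs(back)$role, channelDefs(tab)$role)
    expect_identical(sampleMeta(back)$condition, "stained")

    writeLines(c("1,2", "3,4"), path)
    file.remove(flowAbVal:::metaSidecar(path))
    expect_error(readEventCSV(path), "header")

    writeLines(c("FSC-A,FL1", "1,2", "3,oops"), path)
    expect_error(readEventCSV(path), "row 3, column 2")
})

test_that("a 20,000-event synthetic sample round-trips exactly", {
    s <- generateSample(syntheticSampleSpec(800), seed = 42)
    path <- withr::local_tempfile(fileext = ".csv")
    writeEventCSV(s$table, path)
    back <- readEventCSV(path)
    expect_identical(eventMatrix(back), eventMatrix(s$table))
})

test_that("FCS 3.0 fixtures are read back faithfully", {
    set.seed(9)
    m <- matrix(as.numeric(sample.int(1024, 500)), 100, 5)
    colnames(m) <- c("FSC-A", "FSC-H", "FSC-W", "SSC-A", "FL1")
    path <- withr::local_tempfile(fileext = ".fcs")
    writeMinimalFCS(path, m)
    tab <- readFCS(path)
    expect_s4_class(tab, "EventTable")
    expect_equal(nEvents(tab), 100L)
    expect_equal(ncol(eventMatrix(tab)), 5L)
    # integer intensities are exactly representable in float32
    expect_equal(unname(eventMatrix(tab)), unname(m))
    expect_equal(channelDefs(tab)$role,
                 c("FSC-A", "FSC-H", "FSC-Width", "SSC-A", "fluorescence"))

    # write-read through the CSV path preserves the event matrix
    csv <- withr::local_tempfile(fileext = ".csv")
    writeEventCSV(tab, csv)
    expect_identical(eventMatrix(readEventCSV(csv)), eventMatrix(tab))
})

test_that("degenerate FCS files are rejected with the failing segment", {
    path <- withr::local_tempfile(fileext = ".fcs")
    m <- matrix(numeric(0), 0, 2,
                dimnames = list(NULL, c("FSC-A", "FL1")))
    writeMinimalFCS(path, m, n_tot = 0)
    expect_error(readFCS(path), "empty event segment")

    writeLines("not an fcs file at all, just text padding to spare", path)
    expect_error(readFCS(path), "HEADER|version")

    m2 <- matrix(1:4 + 0, 2, 2, dimnames = list(NULL, c("XYZZY", "FL1")))
    writeMinimalFCS(path, m2)
    expect_error(readFCS(path), "role")
})

test_that("compensation inverts the spillover mixing", {
    m <- cbind(`FSC-A` = c(10, 20), FL1 = c(100, 50), FL2 = c(110, 60))
    tab <- EventTable(m, c(`FSC-A` = "FSC-A", FL1 = "fluorescence",
                           FL2 = "fluorescence"))
    S_id <- SpilloverMatrix(diag(2), c("FL1", "FL2"))
    expect_equal(eventMatrix(compensate(tab, S_id)), eventMatrix(tab))

    # hand inversion of the triangular 2x2: x = (100, 110) -> (100, 100)
    S <- SpilloverMatrix(rbind(c(1, 0.1), c(0, 1)), c("FL1", "FL2"))
    comp <- compensate(tab, S)
    expect_equal(unname(eventMatrix(comp)[1, c("FL1", "FL2")]),
                 c(100, 100))
    expect_true(sampleMeta(comp)$compensated)
    # scatter untouched
    expect_equal(eventMatrix(comp)[, "FSC-A"], eventMatrix(tab)[, "FSC-A"])

    # compensating with S then re-mixing recovers the original
    remixed <- eventMatrix(comp)[, c("FL1", "FL2")] %*% S@values
    expect_equal(remixed, eventMatrix(tab)[, c("FL1", "FL2")],
                 tolerance = 1e-12)
})

test_that("compensation is linear and flags negative results", {
    S <- SpilloverMatrix(rbind(c(1, 0.3), c(0.2, 1)), c("FL1", "FL2"))
    m <- cbind(FL1 = c(50, 200, 5), FL2 = c(80, 10, 400))
    tab <- EventTable(m, c(FL1 = "fluorescence", FL2 = "fluorescence"))
    a <- 3.7
    scaled <- EventTable(a * m, channelDefs(tab))
    expect_equal(eventMatrix(compensate(scaled, S)),
                 a * eventMatrix(compensate(tab, S)))
    qc <- sampleMeta(compensate(tab, S))$qc
    expect_equal(qc$negative_after_compensation,
                 sum(m %*% solve(S@values) < 0))
})

test_that("spillover matrices enforce their invariants", {
    expect_error(SpilloverMatrix(rbind(c(1, 0.5), c(2, 1)),
                                 c("FL1", "FL2")), "0, 1")
    expect_error(SpilloverMatrix(rbind(c(1, 1 - 1e-16), c(1 - 1e-16, 1)),
                                 c("FL1", "FL2")), "invertible|0, 1")
    expect_error(SpilloverMatrix(rbind(c(2, 0), c(0, 1)), c("FL1", "FL2")),
                 "unit diagonal")
    tab <- EventTable(cbind(FL1 = 1:3 + 0),
                      c(FL1 = "fluorescence"))
    S <- SpilloverMatrix(diag(2), c("FL1", "FLX"))
    expect_error(compensate(tab, S), "mapping|not present")
})

test_that("event tables validate roles, negativity and condition labels", {
    expect_error(EventTable(cbind(A = -1), c(A = "fluorescence")),
                 "nonnegative")
    expect_error(EventTable(cbind(A = 1), c(A = "whatever")), "role")
    expect_error(EventTable(cbind(A = 1), c(A = "fluorescence"),
                            meta = list(condition = "mystery")),
                 "condition")
    ok <- EventTable(cbind(A = 1), c(A = "fluorescence"),
                     meta = list(condition = "blocked:tubulin"))
    expect_s4_class(ok, "EventTable")
})
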