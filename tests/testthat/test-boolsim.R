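test_that("parseKgml translates subtypes to signs and expands groups", {
    regs <- data.frame(source = c("A", "C"), target = c("B", "B"),
                       sign = c(1L, -1L))
    got <- parseKgml(makeToyKgml(regs))
    expect_equal(got[order(got$source), ], regs[order(regs$source), ],
                 ignore_attr = TRUE)
    # group entries expand to one regulation per component
    kgml <- paste0(
        '<?xml version="1.0"?><pathway name="p" org="t" number="1">',
        '<entry id="1" name="G1 alias1" type="gene"/>',
        '<entry id="2" name="G2" type="gene"/>',
        '<entry id="3" name="X" type="gene"/>',
        '<entry id="4" name="undefined" type="group">',
        '<component id="1"/><component id="2"/></entry>',
        '<relation entry1="4" entry2="3" type="PPrel">',
        '<subtype name="activation" value="--&gt;"/></relation>',
        '</pathway>')
    got2 <- parseKgml(kgml)
    expect_equal(nrow(got2), 2)
    expect_setequal(got2$source, c("G1", "G2"))   # first name token used
    expect_equal(unique(got2$target), "X")
    expect_equal(unique(got2$sign), 1L)
    # relations without a recognized subtype are skipped with a warning
    kgml3 <- paste0(
        '<?xml version="1.0"?><pathway name="p" org="t" number="1">',
        '<entry id="1" name="A" type="gene"/>',
        '<entry id="2" name="B" type="gene"/>',
        '<relation entry1="1" entry2="2" type="PPrel">',
        '<subtype name="binding/association" value="---"/></relation>',
        '</pathway>')
    expect_warning(got3 <- parseKgml(kgml3), "skipped")
    expect_equal(nrow(got3), 0)
    # unknown entry reference is a structural error
    kgml4 <- paste0(
        '<?xml version="1.0"?><pathway name="p" org="t" number="1">',
        '<entry id="1" name="A" type="gene"/>',
        '<relation entry1="1" entry2="99" type="PPrel">',
        '<subtype name="activation" value="--&gt;"/></relation>',
        '</pathway>')
    expect_error(parseKgml(kgml4), "unknown entry")
    expect_error(parseKgml("<pathway"), "")
})

test_that("assembled rules are OR(activators) AND NOT OR(inhibitors)", {
    regs <- data.frame(source = c("A", "C", "D"), target = c("B", "B", "E"),
                       sign = c(1L, -1L, -1L))
    bn <- assembleBooleanNetwork(regs)
    st <- function(...) {
        v <- c(...)
        booleanStep(bn, v[bnNodes(bn)])
    }
    # B = A AND NOT C
    expect_equal(st(A = 1, C = 0, D = 0, B = 0, E = 0)[["B"]], 1L)
    expect_equal(st(A = 1, C = 1, D = 0, B = 0, E = 0)[["B"]], 0L)
    expect_equal(st(A = 0, C = 0, D = 0, B = 1, E = 0)[["B"]], 0L)
    # E has only an inhibitor: E = NOT D
    expect_equal(st(A = 0, C = 0, D = 0, B = 0, E = 0)[["E"]], 1L)
    expect_equal(st(A = 0, C = 0, D = 1, B = 0, E = 1)[["E"]], 0L)
    # inputs are constant
    expect_equal(st(A = 1, C = 0, D = 1, B = 0, E = 0)[["A"]], 1L)
    # contradictory regulation: inhibitor dominates, reported
    expect_message(bn2 <- assembleBooleanNetwork(
        data.frame(source = c("A", "A"), target = "B", sign = c(1L, -1L))),
        "dominates")
    expect_equal(booleanStep(bn2, c(A = 1, B = 0))[["B"]], 0L)
})

test_that("synchronous dynamics reach fixed points and limit cycles", {
    # chain A -> B -> C
    chain <- assembleBooleanNetwork(
        data.frame(source = c("A", "B"), target = c("B", "C"), sign = 1L))
    s <- c(A = 1, B = 0, C = 0)
    s <- booleanStep(chain, s); s <- booleanStep(chain, s)
    expect_equal(unname(s), c(1L, 1L, 1L))
    expect_equal(booleanStep(chain, s), s)      # fixed point stays fixed
    # 3-node inhibition ring: exhaustively walk all 2^3 states and find the
    # unique attractor cycle
    ring <- assembleBooleanNetwork(
        data.frame(source = c("A", "B", "C"), target = c("B", "C", "A"),
                   sign = -1L))
    states <- expand.grid(A = 0:1, B = 0:1, C = 0:1)
    key <- function(v) paste(v, collapse = "")
    cycleLens <- integer(0)
    for (i in seq_len(nrow(states))) {
        s <- unlist(states[i, ]); seen <- character(0)
        repeat {
            k <- key(s)
            if (k %in% seen) {
                cycleLens <- c(cycleLens,
                               length(seen) - match(k, seen) + 1L)
                break
            }
            seen <- c(seen, k)
            s <- booleanStep(ring, s[bnNodes(ring)])
        }
    }
    expect_true(all(cycleLens > 1))   # no fixed point: genuine limit cycle
    expect_error(booleanStep(chain, c(1, 0)), "length")
})

test_that("multilinear interpolation matches AND/OR values mid-cube", {
    andNet <- assembleBooleanNetwork(data.frame(
        source = c("A", "B"), target = "T", sign = 1L))
    # T = A OR B: at (0.5, 0.5) the interpolation is 0.75
    m <- continuousModel(andNet, "boolecube", tau = 1)
    x <- c(A = 0.5, B = 0.5, T = 0)
    expect_equal(unname(continuousRate(m, x)[["T"]]), 0.75)
    # an AND appears as activator + double negation: T2 = A AND NOT I with
    # I = NOT B gives multilinear value a*b at corners' interpolation
    and2 <- assembleBooleanNetwork(data.frame(
        source = c("A", "I"), target = c("T", "T"), sign = c(1L, -1L)))
    m2 <- continuousModel(and2, "boolecube")
    # B~_T(x) = A * (1 - I): at A = 0.5, I = 0.5 -> 0.25
    expect_equal(unname(continuousRate(
        m2, c(A = 0.5, I = 0.5, T = 0))[["T"]]), 0.25)
    # Hill function passes through one half at its threshold
    for (n in c(1, 2, 3, 7)) {
        hb <- assembleBooleanNetwork(data.frame(source = "A", target = "T",
                                                sign = 1L))
        mh <- continuousModel(hb, "hillcube", hillN = n, hillK = 0.3)
        expect_equal(unname(continuousRate(
            mh, c(A = 0.3, T = 0))[["T"]]), 0.5)
    }
})

test_that("interpolations agree with the Boolean rule on every corner", {
    # all rule shapes with <= 3 regulators: |activators| + |inhibitors| <= 3
    shapes <- expand.grid(nAct = 0:3, nInh = 0:3)
    shapes <- shapes[shapes$nAct + shapes$nInh <= 3 &
                     shapes$nAct + shapes$nInh > 0, ]
    for (r in seq_len(nrow(shapes))) {
        na <- shapes$nAct[r]; ni <- shapes$nInh[r]
        acts <- if (na) paste0("a", seq_len(na)) else character(0)
        inhs <- if (ni) paste0("i", seq_len(ni)) else character(0)
        regs <- data.frame(source = c(acts, inhs), target = "T",
                           sign = c(rep(1L, na), rep(-1L, ni)))
        bn <- assembleBooleanNetwork(regs)
        corners <- expand.grid(rep(list(0:1), na + ni))
        names(corners) <- c(acts, inhs)
        for (method in c("boolecube", "normalized_hillcube")) {
            m <- continuousModel(bn, method)
            for (i in seq_len(nrow(corners))) {
                x <- stats::setNames(numeric(length(bnNodes(bn))),
                                     bnNodes(bn))
                x[names(corners)] <- unlist(corners[i, ])
                boolNext <- booleanStep(bn, x[bnNodes(bn)])[["T"]]
                contTarget <- continuousRate(m, x)[["T"]] + x[["T"]]
                expect_equal(unname(contTarget), boolNext,
                             tolerance = 1e-12)
            }
        }
    }
})

test_that("Boolean fixed points are stationary and [0,1]^n is invariant", {
    set.seed(8)
    regs <- makeRandomRegulations(12, 18, seed = 9)
    bn <- assembleBooleanNetwork(regs)
    nodes <- bnNodes(bn)
    # find synchronous fixed points by sampling + iteration
    for (i in 1:20) {
        s <- stats::setNames(rbinom(length(nodes), 1, 0.5), nodes)
        for (j in 1:50) s <- booleanStep(bn, s)
        if (identical(booleanStep(bn, s), s)) {
            m <- continuousModel(bn, "boolecube")
            expect_lt(max(abs(continuousRate(m, as.numeric(s)))), 1e-9)
        }
    }
    # trajectories never exit the unit cube
    m <- continuousModel(bn, "normalized_hillcube")
    x0 <- stats::setNames(runif(length(nodes)), nodes)
    traj <- integrateModel(m, x0, horizon = 10)
    vals <- traj[, -1]
    expect_true(all(vals >= -1e-6 & vals <= 1 + 1e-6))
})

test_that("integration follows the closed-form relaxation under clamping", {
    bn <- assembleBooleanNetwork(data.frame(source = "A", target = "B",
                                            sign = 1L))
    m <- continuousModel(bn, "boolecube", tau = 1)
    x0 <- c(A = 1, B = 0.2)
    traj <- integrateModel(m, x0, horizon = 5, clamp = "A",
                           times = seq(0, 5, 0.5))
    # with A clamped at 1: x_B(t) = 1 - (1 - x_B(0)) exp(-t)
    expect_equal(traj[, "B"], 1 - 0.8 * exp(-traj[, "time"]),
                 tolerance = 1e-6, ignore_attr = TRUE)
    expect_equal(unname(traj[, "A"]), rep(1, nrow(traj)))
    # input node stays constant without clamping
    traj2 <- integrateModel(m, c(A = 0.37, B = 1), horizon = 3)
    expect_equal(unname(traj2[nrow(traj2), "A"]), 0.37, tolerance = 1e-8)
    # a Boolean fixed point yields a stationary trajectory
    traj3 <- integrateModel(m, c(A = 0, B = 0), horizon = 3)
    expect_lt(max(abs(traj3[nrow(traj3), -1])), 1e-8)
    expect_error(integrateModel(m, c(A = 2, B = 0)), "\\[0,1\\]")
})

test_that("treatment simulation counts switches and is reproducible", {
    bn <- assembleBooleanNetwork(data.frame(source = "A", target = "B",
                                            sign = 1L))
    r1 <- simulateTreatment(bn, c(A = 1), nSims = 300, seed = 42)
    r2 <- simulateTreatment(bn, c(A = 1), nSims = 300, seed = 42)
    expect_identical(switchRanking(r1), switchRanking(r2))
    # treatment nodes are excluded from the ranking
    expect_false("A" %in% switchRanking(r1)$node)
    # B switches exactly when initialized at 0: frequency ~ 1/2
    f <- switchRanking(r1)$frequency[switchRanking(r1)$node == "B"]
    expect_lt(abs(f - 0.5), 3 * sqrt(0.25 / 300))
    # an isolated input node never switches
    bn2 <- assembleBooleanNetwork(
        data.frame(source = "A", target = "B", sign = 1L),
        nodes = c("A", "B", "LONE"))
    r3 <- simulateTreatment(bn2, c(A = 1), nSims = 100, seed = 7)
    expect_equal(switchRanking(r3)$frequency[
        switchRanking(r3)$node == "LONE"], 0)
    expect_error(simulateTreatment(bn, c(Q = 1)), "unknown treatment")
})

test_that("switch frequencies are invariant to node-order permutation", {
    regs <- data.frame(source = c("A", "B", "C"), target = c("B", "C", "D"),
                       sign = c(1L, -1L, 1L))
    bn1 <- assembleBooleanNetwork(regs, nodes = c("A", "B", "C", "D"))
    bn2 <- assembleBooleanNetwork(regs, nodes = c("D", "C", "B", "A"))
    r1 <- switchRanking(simulateTreatment(bn1, c(A = 1), nSims = 150,
                                          seed = 5))
    r2 <- switchRanking(simulateTreatment(bn2, c(A = 1), nSims = 150,
                                          seed = 5))
    expect_identical(r1, r2)
})
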