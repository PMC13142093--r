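test_that("crafted conformation gives exactly the designed contacts", {
  cc <- fixture("crafted_contacts")
  bp <- attr(cc, "genomic_bead") * 10L          # 10 bp per bead
  m <- detect_contacts(cc$positions, bp, coord_span = 4000)
  expect_equal(m$n_segments, 4L)
  expect_equal(m$kind, "binary")
  want <- diag(4)
  want[1, 2] <- want[2, 1] <- 1                  # the single 5-nm pair
  expect_equal(m$values, want)
})

test_that("straight chain contacts only adjacent segments", {
  # 300 beads at 3.4 nm spacing, 100 beads (1 kb) per segment: within a
  # segment and across each boundary distances < 6 nm exist; segments two
  # apart are >= 340 nm away
  ch <- fixture("straight_chain", list(n = 300, spacing = 3.4))
  bp <- (seq_len(300) - 1L) * 10L
  m <- detect_contacts(ch$positions, bp, coord_span = 3000)
  expect_equal(m$n_segments, 3L)
  want <- matrix(c(1, 1, 0, 1, 1, 1, 0, 1, 1), 3, 3)
  expect_equal(m$values, want)
})

test_that("voxelized detection equals the all-pairs oracle", {
  set.seed(31)
  for (trial in list(
    list(n = 200, box = 30),    # dense: many contacts
    list(n = 500, box = 150),   # moderate
    list(n = 300, box = 800)    # sparse: few or none
  )) {
    pos <- matrix(runif(3 * trial$n, 0, trial$box), ncol = 3)
    bp <- sort(sample(0:9999, trial$n))
    a <- detect_contacts(pos, bp, coord_span = 10000)
    b <- detect_contacts_bruteforce(pos, bp, coord_span = 10000)
    expect_identical(a$values, b$values)
  }
  # boundary case: pair exactly at the cutoff is not a contact (strict <)
  pos <- rbind(c(0, 0, 0), c(6, 0, 0), c(0, 0, 100), c(5.999, 0, 100))
  m <- detect_contacts(pos, c(0, 1000, 2000, 3000), coord_span = 4000)
  expect_equal(m$values[1, 2], 0)
  expect_equal(m$values[3, 4], 1)
})

test_that("aggregation sums binary maps and rejects mismatches", {
  set.seed(32)
  mats <- lapply(1:4, function(k) {
    pos <- matrix(runif(60, 0, 25), ncol = 3)
    detect_contacts(pos, (0:19) * 100, coord_span = 2000)
  })
  agg <- aggregate_contacts(mats)
  expect_equal(agg$kind, "counts")
  expect_equal(agg$values, Reduce(`+`, lapply(mats, `[[`, "values")))
  expect_equal(diag(agg$values), rep(4, 2))     # unit diagonals accumulate
  expect_true(max(agg$values) <= 4)
  bad <- detect_contacts(matrix(runif(30, 0, 25), ncol = 3),
                         (0:9) * 100, coord_span = 1000)
  expect_error(aggregate_contacts(list(mats[[1]], bad)), "mismatched")
})

test_that("Knight-Ruiz balancing", {
  # closed form for [[2,1],[1,2]]
  b <- kr_balance(matrix(c(2, 1, 1, 2), 2, 2))
  expect_equal(b$values, matrix(c(2, 1, 1, 2), 2, 2) / 3, tolerance = 1e-6)
  expect_equal(attr(b, "scaling"), rep(1 / sqrt(3), 2), tolerance = 1e-6)

  # random symmetric positive matrices: row and column sums within 1e-6 of 1
  set.seed(33)
  for (n in c(10, 60)) {
    A <- matrix(runif(n * n, 0.05, 1), n, n)
    A <- A + t(A)
    out <- kr_balance(A)
    expect_lt(max(abs(rowSums(out$values) - 1)), 1e-6)
    expect_lt(max(abs(colSums(out$values) - 1)), 1e-6)
    expect_true(isSymmetric(out$values))
    # idempotence: balancing a balanced matrix changes nothing material
    again <- kr_balance(out$values)
    expect_equal(again$values, out$values, tolerance = 1e-5)
  }

  # doubly stochastic input is a fixed point
  ds <- matrix(c(0.5, 0.5, 0.5, 0.5), 2, 2)
  expect_equal(kr_balance(ds)$values, ds, tolerance = 1e-9)

  # zero rows are carried through as zeros with NA scaling
  Z <- matrix(c(2, 0, 1, 0, 0, 0, 1, 0, 2), 3, 3)
  bz <- kr_balance(Z)
  expect_equal(bz$values[2, ], rep(0, 3))
  expect_true(is.na(attr(bz, "scaling")[2]))
  expect_lt(max(abs(rowSums(bz$values)[c(1, 3)] - 1)), 1e-6)

  expect_error(kr_balance(matrix(c(1, 2, 3, 4), 2, 2)), "symmetric")
})

test_that("contact probability curve", {
  # uniform matrix: flat curve at its value
  m <- contact_matrix(matrix(0.25, 8, 8), kind = "counts")
  pc <- contact_probability_curve(m)
  expect_equal(pc$s, (0:4) * 1000)
  expect_equal(pc$p, rep(0.25, 5))

  # circular band matrix: contacts only at distance 1
  n <- 10
  B <- diag(n)
  for (i in seq_len(n)) {
    B[i, (i %% n) + 1] <- 1
    B[(i %% n) + 1, i] <- 1
  }
  pb <- contact_probability_curve(contact_matrix(B, kind = "counts"))
  expect_equal(pb$p, c(1, 1, 0, 0, 0, 0))

  # enumeration oracle on a random symmetric circulant-agnostic matrix
  set.seed(34)
  V <- matrix(runif(49), 7, 7)
  V <- (V + t(V)) / 2
  pr <- contact_probability_curve(contact_matrix(V, kind = "counts"))
  for (k in 0:3) {
    vals <- sapply(1:7, function(i) V[i, ((i - 1 + k) %% 7) + 1])
    expect_equal(pr$p[k + 1], mean(vals))
  }
})

test_that("replicating layout assigns daughter coordinates past L", {
  g <- init_genome(10000, 10)
  st0 <- replication_state(g)
  lay0 <- replicating_map_layout(st0)
  expect_equal(lay0$coord_span, 10000L)
  expect_equal(lay0$bead_bp, (0:999) * 10L)

  st <- advance_forks(st0, 30L)
  lay <- replicating_map_layout(st)
  expect_equal(lay$coord_span, 20000L)
  expect_length(lay$bead_bp, st$n_dna_beads)
  # mother/dL slots keep their coordinates
  expect_equal(lay$bead_bp[1:1000], (0:999) * 10L)
  # each right-daughter slot maps to L + its mother coordinate
  for (gpos in which(st$replicated) - 1L) {
    slot <- st$dr_slot[gpos + 1L]
    expect_equal(lay$bead_bp[slot], 10000L + gpos * 10L)
  }
  # fully replicated genome spans exactly [0, 2L)
  while (!st$complete) st <- advance_forks(st, 30L)
  expect_true(st$complete)
  layf <- replicating_map_layout(st)
  expect_setequal(layf$bead_bp, (0:1999) * 10L)
})
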