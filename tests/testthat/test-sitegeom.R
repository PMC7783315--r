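test_that("coordinate mapping reproduces published conversions and round-trips", {
  expect_identical(map_coordinates(433L, "SK11_mature", "MS22337_orf"), 618L)
  expect_identical(map_coordinates(748L, "SK11_mature", "MS22337_orf"), 933L)
  expect_identical(map_coordinates(1L, "MS22337_mature", "MS22337_orf"), 186L)
  expect_identical(map_coordinates(99L, "fig1_map", "fig1_map"), 99L)
  # round-trip over every scheme pair
  schemes <- names(coordinate_schemes())
  for (from in schemes) for (to in schemes) {
    x <- 250L
    expect_identical(map_coordinates(map_coordinates(x, from, to), to, from), x)
  }
  # per-call offset override (+186 variant)
  expect_identical(map_coordinates(205L, "SK11_mature", "MS22337_orf",
                                   from_offset = 186L), 391L)
  expect_error(map_coordinates(1L, "MS22337_orf", "MS22337_mature"), "below 1")
  expect_error(map_coordinates(5L, "nope", "MS22337_orf"), "unknown scheme")
})

test_that("domain annotation keeps the triad inside the proteinase core", {
  dom <- prtp_domains()
  pr <- dom[dom$domain == "PR", ]
  expect_identical(c(pr$start, pr$end), c(186L, 698L))
  expect_true(all(c(215, 279, 618) >= pr$start & c(215, 279, 618) <= pr$end))
  expect_true(all(dom$start <= dom$end))
  expect_identical(pr$end - pr$start + 1L, 513L)
})

test_that("triad distances reproduce a 3-4-5 triangle exactly", {
  m <- chain_model("tri", "MS22337_orf", c(215L, 279L, 618L), c("D", "H", "S"),
                   rbind(c(0, 0, 0), c(3, 0, 0), c(3, 4, 0)))
  g <- triad_distances(m)
  expect_equal(g$d_h, 3)
  expect_equal(g$h_s, 4)
  expect_equal(g$d_s, 5)
  # triangle inequality
  expect_lt(g$d_s, g$d_h + g$h_s)
  expect_error(triad_distances(chain_subset(m, c(215L, 618L))), "279")
})

test_that("triad distances can use functional side-chain atoms when present", {
  extra <- data.frame(seq_index = c(618L, 279L, 215L),
                      atom = c("OG", "NE2", "CG"),
                      x = c(3, 3, 0), y = c(3, 0, 1), z = c(0, 0, 0))
  m <- chain_model("tri", "MS22337_orf", c(215L, 279L, 618L), c("D", "H", "S"),
                   rbind(c(0, 0, 0), c(10, 0, 0), c(20, 0, 0)), extra)
  g <- triad_distances(m, triad_spec(atom_rule = "functional_atom"))
  expect_equal(g$d_h, sqrt(10))   # CG(0,1,0) to NE2(3,0,0)
  expect_equal(g$h_s, 3)          # NE2(3,0,0) to OG(3,3,0)
  # with CA rule the stretched backbone distances are used instead
  expect_equal(triad_distances(m)$d_h, 10)
})

test_that("triad classification thresholds and monotonicity behave", {
  g6 <- structure(list(d_s = 7, d_h = 6, h_s = 6, model_id = "a"),
                  class = "TriadGeometry")
  g18 <- structure(list(d_s = 7, d_h = 16, h_s = 18, model_id = "b"),
                   class = "TriadGeometry")
  expect_identical(classify_triad(g6)$state, "assembled")
  expect_identical(classify_triad(g18)$state, "displaced")
  # boundary case: exactly at threshold counts as assembled
  gb <- structure(list(d_s = 7, d_h = 9, h_s = 10, model_id = "c"),
                  class = "TriadGeometry")
  expect_identical(classify_triad(gb)$state, "assembled")
  expect_equal(classify_triad(gb)$margin, 0)
  # increasing h_s can never flip displaced back to assembled
  states <- vapply(seq(5, 20, by = 0.5), function(hs) {
    classify_triad(structure(list(d_s = 7, d_h = 6, h_s = hs, model_id = "x"),
                             class = "TriadGeometry"))$state
  }, character(1))
  expect_true(!is.unsorted(match(states, c("assembled", "displaced"))))
})

test_that("distances are invariant under rigid transforms of the model", {
  fx <- make_triad_fixture("assembled", seed = 31)
  g0 <- triad_distances(fx$model)
  d0 <- residue_pair_distance(fx$model, 215L, 618L)
  for (s in 1:5) {
    moved <- random_rigid_move(fx$model, s)$model
    g <- triad_distances(moved)
    expect_equal(c(g$d_s, g$d_h, g$h_s), c(g0$d_s, g0$d_h, g0$h_s),
                 tolerance = 1e-9)
    expect_equal(residue_pair_distance(moved, 215L, 618L), d0, tolerance = 1e-9)
  }
  expect_equal(residue_pair_distance(fx$model, 215L, 215L), 0)
  expect_error(residue_pair_distance(fx$model, 215L, 9999L), "9999")
})

test_that("ensemble triad report counts planted states and flags missing residues", {
  models <- c(lapply(1:4, function(s) make_triad_fixture("assembled", s)$model),
              lapply(5:6, function(s) make_triad_fixture("displaced", s)$model))
  rep_ <- ensemble_triad_report(models)
  expect_identical(nrow(rep_), 6L)
  s <- attr(rep_, "summary")
  expect_identical(unname(s[c("assembled", "displaced")]), c(4L, 2L))
  expect_true(all(abs(rep_$d_s - 7) < 0.01))

  # model missing the histidine: flagged row, not an error
  broken <- chain_subset(models[[1]], setdiff(models[[1]]$seq_index, 279L))
  rep2 <- ensemble_triad_report(c(models[1], list(broken)))
  expect_identical(attr(rep2, "summary")[["missing"]], 1L)
  expect_true(is.na(rep2$state[2]))
  # single model -> one row
  expect_identical(nrow(ensemble_triad_report(models[1])), 1L)
})

test_that("extent measures the principal-axis span and is rotation invariant", {
  two <- chain_model("two", "MS22337_orf", 1:2, c("A", "A"),
                     rbind(c(0, 0, 0), c(100, 0, 0)))
  expect_equal(estimate_extent(two), 100)
  rod <- make_helix_rod(100, rise = 1.5, radius = 0)
  expect_equal(estimate_extent(rod), 148.5)
  helix <- make_helix_rod(100)
  expect_equal(estimate_extent(helix), 148.5, tolerance = 0.01)
  for (s in 1:5) {
    expect_equal(estimate_extent(random_rigid_move(helix, s)$model),
                 estimate_extent(helix), tolerance = 1e-6)
  }
  degenerate <- chain_model("d", "MS22337_orf", 1:3, rep("A", 3), matrix(1, 3, 3))
  expect_error(estimate_extent(degenerate), "degenerate")
})

test_that("axial domain assembly stacks rods with the requested gap", {
  a <- make_helix_rod(100, start_index = 1L, model_id = "a")
  b <- make_helix_rod(100, start_index = 200L, model_id = "b")
  asm <- assemble_domains(list(a, b), gap = 3)
  expect_identical(length(asm), 200L)
  expect_equal(estimate_extent(asm), 2 * 148.5 + 3, tolerance = 1)
  expect_gte(estimate_extent(asm) + 2,
             estimate_extent(a) + estimate_extent(b))
  # single domain: extent preserved up to rigid transform
  one <- assemble_domains(list(a))
  expect_equal(estimate_extent(one), estimate_extent(a), tolerance = 1e-6)
  # out-of-order or overlapping ranges are rejected
  expect_error(assemble_domains(list(b, a)), "order")
  c_ <- make_helix_rod(100, start_index = 50L, model_id = "c")
  expect_error(assemble_domains(list(a, c_)), "order")
})
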