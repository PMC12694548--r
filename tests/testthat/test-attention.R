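# Attention blocks: shape preservation, gating bounds, axis structure,
# CA swap-in, and budget ordering.

test_that("every attention kind preserves shape on non-square inputs", {
  x <- rand_ft(6, 9, 16, 2, seed = 1)
  for (kind in c("se", "eca", "cbam", "ca")) {
    set.seed(3)
    blk <- attention_block(kind, 16)
    y <- eng_fwd(blk, x, train = FALSE)$y
    expect_equal(dim(y), dim(x), label = kind)
    expect_equal(vitileaf:::ft_dim(y), vitileaf:::ft_dim(x))
  }
})

test_that("SE gating strictly shrinks magnitudes (gates in (0,1))", {
  set.seed(11)
  blk <- attention_block("se", 8)
  pars <- eng_params(blk)
  pars[["m.fc2.b"]][] <- 0.5   # keep pre-activations inside the open interval
  pars[["m.fc2.w"]] <- pars[["m.fc2.w"]] * 0.1
  blk <- eng_set(blk, pars)
  for (s in 1:5) {
    x <- rand_ft(4, 4, 8, 2, seed = s)
    y <- eng_fwd(blk, x)$y
    expect_true(all(abs(y) <= abs(unclass(x)) + 1e-12))
    nz <- abs(x) > 1e-8
    expect_true(all(abs(y)[nz] > 0))           # gates never reach exactly 0
  }
})

test_that("squeeze of a channel-constant input is that constant", {
  x <- ft(matrix(rep(c(2, -1, 0.5), each = 24), 24, 3), 4, 3, 2)
  d <- vitileaf:::ft_dim(x)
  grp <- vitileaf:::sample_groups(d[1], d[2], d[3])
  sq <- vitileaf:::group_mean(x, grp, d[1] * d[2])
  expect_equal(unname(sq), matrix(c(2, -1, 0.5), 2, 3, byrow = TRUE))
})

test_that("coordinate attention emits an axis-constant gate when the input is", {
  set.seed(5)
  blk <- attention_block("ca", 4)
  # input constant over W, varying over H
  H <- 6; W <- 5
  base <- matrix(stats::rnorm(H * 4), H, 4)
  m <- base[rep(seq_len(H), W), ]
  x <- ft(m, H, W, 1)
  r <- vitileaf:::ca_fwd(blk, x, train = FALSE)
  gw <- r$cache$gw                 # (W x C) gate along the width axis
  expect_lt(max(abs(sweep(gw, 2, gw[1, ]))), 1e-12)
  # and the full map is identical for every width position
  y <- ft_to_array(r$y)
  expect_lt(max(abs(y[, 2:W, , 1] - y[, 1:(W - 1), , 1])), 1e-12)
})

test_that("ECA is orders of magnitude lighter than SE at equal channels", {
  se_p <- vitileaf:::n_params_of(attention_block("se", 576))
  eca_p <- vitileaf:::n_params_of(attention_block("eca", 576))
  expect_lt(eca_p, 10)
  expect_gt(se_p / eca_p, 1000)
})

test_that("make_ca_block swaps SE rows and leaves others untouched", {
  rows <- mnv3_small_rows()
  out <- make_ca_block(rows)
  expect_true(all(out$attention[rows$attention == "se"] == "ca"))
  expect_identical(out$attention[rows$attention == "none"],
                   rows$attention[rows$attention == "none"])
  expect_identical(out[, setdiff(names(out), "attention")],
                   rows[, setdiff(names(rows), "attention")])
  no_se <- rows[rows$attention == "none", ]
  expect_warning(out2 <- make_ca_block(no_se), "unchanged")
  expect_identical(out2, no_se)
})

test_that("whole-model budgets order as the published table prints them", {
  p <- vapply(c("ICS-MS-CE", "MS-CA", "MS-CBAM", "MS"),
              function(v) params_millions(count_parameters(v)), 0)
  expect_identical(unname(p), c(1.12, 1.37, 1.52, 1.53))
  expect_true(all(diff(p) > 0))
})

test_that("attention gate values lie strictly inside (0,1)", {
  set.seed(9)
  x <- rand_ft(5, 5, 8, 3, seed = 2)
  se <- attention_block("se", 8)
  r <- vitileaf:::se_fwd(se, x, FALSE)
  expect_true(all(r$cache$g >= 0 & r$cache$g <= 1))
  ca <- attention_block("ca", 8)
  rc <- vitileaf:::ca_fwd(ca, x, FALSE)
  expect_true(all(rc$cache$gh >= 0 & rc$cache$gh <= 1))
  expect_true(all(rc$cache$gw >= 0 & rc$cache$gw <= 1))
})
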