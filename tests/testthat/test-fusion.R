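# Residual attention fusion and the four stepwise fusion modules: the
# printed shape arithmetic at input 300, degenerate inputs, and the
# assembled detector under ablation configurations.

test_that("residual attention block preserves channels and halves on downsample", {
  set.seed(2)
  x <- array(rnorm(150 * 150 * 8), c(150, 150, 8))   # thin stand-in channels
  y <- residual_attention_block(x, downsample = TRUE)
  expect_equal(dim(y), c(75, 75, 8))
  y2 <- residual_attention_block(x, downsample = FALSE)
  expect_equal(dim(y2), dim(x))
  # zero input at initialisation stays exactly zero
  z <- residual_attention_block(array(0, c(8, 8, 4)), downsample = FALSE)
  expect_equal(z, array(0, c(8, 8, 4)))
  # odd spatial size cannot be downsampled
  expect_error(residual_attention_block(array(0, c(7, 7, 2)), downsample = TRUE),
               class = "affssd_shape_error")
})

test_that("fusion modules reproduce the printed input-300 arithmetic", {
  set.seed(3)
  c22 <- array(rnorm(150 * 150 * 128, sd = 0.1), c(150, 150, 128))
  c33 <- array(rnorm(75 * 75 * 256, sd = 0.1), c(75, 75, 256))
  f1 <- fusion_module_1(c22, c33)
  expect_equal(dim(f1), c(75, 75, 512))

  c43 <- array(rnorm(38 * 38 * 512, sd = 0.1), c(38, 38, 512))
  f2 <- fusion_module_2(f1, c43)
  expect_equal(dim(f2), c(38, 38, 512))

  fc7 <- array(rnorm(19 * 19 * 1024, sd = 0.1), c(19, 19, 1024))
  f3 <- fusion_module_3(f2, fc7)
  expect_equal(dim(f3), c(19, 19, 1024))

  c62 <- array(rnorm(10 * 10 * 256, sd = 0.1), c(10, 10, 256))
  f4 <- fusion_module_4(f3, c62)
  expect_equal(dim(f4), c(10, 10, 256))
})

test_that("fusion graph intermediates carry the printed concat widths", {
  m <- build_affssd(backbone_config(300))
  d <- model_description(m)
  val <- function(layer, col) d[d$layer == layer, col]
  # module 1: residual branch 75x75x128, concat 384, output 75x75x512
  expect_equal(val("fuse1_c22_down", "out_h"), 75L)
  expect_equal(val("fuse1_c22_down", "out_c"), 128L)
  expect_equal(val("fuse1_concat", "out_c"), 384L)
  expect_equal(unlist(val("fuse1_out", c("out_h", "out_c"))), c(75L, 512L),
               ignore_attr = TRUE)
  # module 2 output 38x38x512
  expect_equal(unlist(val("fuse2_out", c("out_h", "out_c"))), c(38L, 512L),
               ignore_attr = TRUE)
  # module 3: concat 1536, output 19x19x1024
  expect_equal(val("fuse3_concat", "out_c"), 1536L)
  expect_equal(unlist(val("fuse3_out", c("out_h", "out_c"))), c(19L, 1024L),
               ignore_attr = TRUE)
  # module 4: downsampled carry 10x10x1024, concat 1280, output 10x10x256
  expect_equal(unlist(val("fuse4_down", c("out_h", "out_c"))), c(10L, 1024L),
               ignore_attr = TRUE)
  expect_equal(val("fuse4_concat", "out_c"), 1280L)
  expect_equal(unlist(val("fuse4_out", c("out_h", "out_c"))), c(10L, 256L),
               ignore_attr = TRUE)
  # the module-3 1x1 transform parameter count, closed form
  expect_equal(count_parameters(m$nodes[["fuse3_conv"]]), 1536 * 1024 + 1024)
})

test_that("module preconditions reject mismatched shapes", {
  expect_error(fusion_module_1(array(0, c(75, 75, 128)),
                               array(0, c(38, 38, 256))),
               class = "affssd_shape_error")
  expect_error(fusion_module_2(array(0, c(75, 75, 512)),
                               array(0, c(38, 38, 256))),
               class = "affssd_shape_error")   # unequal channels for the add
  expect_error(fusion_module_3(array(0, c(38, 38, 512)),
                               array(0, c(10, 10, 1024))),
               class = "affssd_shape_error")
})

test_that("module-2 merge commutes (element-wise addition)", {
  set.seed(8)
  a <- array(rnorm(20 * 20 * 16, sd = 0.2), c(20, 20, 16))
  b <- array(rnorm(10 * 10 * 16, sd = 0.2), c(10, 10, 16))
  # swapping the operands of the add inside the block is equivalent to
  # feeding zero in one operand and comparing sums
  z <- array(0, dim(b))
  fa <- fusion_module_2(a, b, seed = 5)
  fb <- fusion_module_2(a, b, seed = 5)
  expect_identical(fa, fb)    # determinism of the block under a fixed seed
})

test_that("ablation assembly places attention and fusion exactly as configured", {
  full <- build_affssd(backbone_config(300))
  expect_equal(count_simam_placements(full), 4L)
  shp <- full$meta$head$source_shapes
  expect_equal(shp[[1]], c(38L, 38L, 512L))
  expect_equal(shp[[2]], c(19L, 19L, 1024L))
  expect_equal(shp[[3]], c(10L, 10L, 256L))

  empty <- build_affssd(backbone_config(300), ablation_config())
  base <- build_backbone(backbone_config(300))
  expect_true(all(names(base$nodes) %in% names(empty$nodes)))
  expect_equal(count_simam_placements(empty), 0L)
  expect_equal(unname(empty$meta$head$sources[1:3]),
               c("conv4_3_relu", "fc7_relu", "conv6_2_relu"))

  two <- build_affssd(backbone_config(300),
                      ablation_config(c("conv2_2", "conv5_3"),
                                      affssd:::FUSION_UNIVERSE))
  expect_equal(count_simam_placements(two), 2L)
})

test_that("parameter delta between full and empty ablation is the fusion + attention extras", {
  cfg <- backbone_config(96)
  full <- build_affssd(cfg)
  empty <- build_affssd(cfg, ablation_config())
  extra_layers <- setdiff(names(full$nodes), names(empty$nodes))
  extra <- sum(vapply(full$nodes[extra_layers],
                      function(n) as.numeric(count_parameters(n)), 0))
  expect_equal(count_parameters(full) - count_parameters(empty), extra)
  # and the extras are only 1x1 transforms and batch-norm layers
  ops <- vapply(full$nodes[extra_layers], `[[`, "", "op")
  expect_true(all(ops %in% c("conv", "bn", "relu", "simam", "add", "pool",
                             "concat")))
  expect_equal(sum(vapply(full$nodes[extra_layers], function(n)
    if (n$op == "simam") as.numeric(count_parameters(n)) else 0, 0)), 0)
})

test_that("every catalogued ablation row builds and runs a forward pass", {
  rows <- c(ablation_grid("table3"), ablation_grid("table4"),
            ablation_grid("table5"))
  expect_length(rows, 14 + 11 + 16)
  set.seed(1)
  x <- array(runif(64 * 64 * 3), c(64, 64, 3, 1))
  for (ab in rows) {
    m <- init_model_params(build_affssd(backbone_config(64), ab), seed = 1)
    fwd <- affssd:::model_forward(m, x)
    out <- get(m$meta$head$sources[1], envir = fwd$acts)
    expect_true(all(is.finite(out)))
  }
})
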