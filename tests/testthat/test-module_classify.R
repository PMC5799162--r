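# small labeled fixture: a left facial module, its mirror, and a vocal-fold
# module, built in code
facial_fixture <- function() {
  left_m <- c("orbicularis_oris_L", "zygomaticus_major_L", "buccinatorius_L")
  right_m <- sub("_L$", "_R", left_m)
  left_b <- c("maxilla_L", "zygomatic_L")
  right_b <- sub("_L$", "_R", left_b)
  vocal <- c("arytenoid_cartilage_L", "arytenoid_cartilage_R",
             "arytenoideus_transversus", "vocalis_L", "vocalis_R")
  nodes <- c(left_m, right_m, left_b, right_b, vocal)
  meta <- toy_meta(nodes)
  meta$tissue <- ifelse(nodes %in% c(left_m, right_m) |
                          grepl("vocalis|transversus", nodes), "muscle",
                 ifelse(grepl("cartilage", nodes), "cartilage", "bone"))
  meta$group <- ifelse(meta$tissue == "muscle" & nodes %in% c(left_m, right_m),
                       "hyoid",
                ifelse(meta$tissue == "muscle", "branchial", "skeletal"))
  meta$is_facial_expression <- nodes %in% c(left_m, right_m)
  edges <- rbind(
    cbind(left_m, "maxilla_L"), cbind(left_m, "zygomatic_L"),
    cbind(right_m, "maxilla_R"), cbind(right_m, "zygomatic_R"),
    cbind(c("vocalis_L", "arytenoideus_transversus"), "arytenoid_cartilage_L"),
    cbind(c("vocalis_R", "arytenoideus_transversus"), "arytenoid_cartilage_R"),
    c("maxilla_L", "maxilla_R"))
  net <- anatomical_network(nodes, edges, meta, taxon_id = "toy")
  assign <- setNames(ifelse(nodes %in% c(left_m, left_b), 0,
                     ifelse(nodes %in% c(right_m, right_b), 1, 2)), nodes)
  list(net = net, assign = assign, meta = meta)
}

test_that("a pure left facial module is labeled left_facial and symmetric", {
  fx <- facial_fixture()
  part <- as_partition(fx$assign, fx$net)
  pr <- profile_module(fx$net, part, 0)
  expect_equal(pr$label, "left_facial")
  expect_false(pr$asymmetric)
  expect_equal(pr$size, 5)
  expect_equal(sum(pr$tissue_counts), pr$size)
  expect_equal(sum(pr$side_counts), pr$size)
  expect_equal(pr$facial_muscle_count, 3)
  expect_equal(profile_module(fx$net, part, 1)$label, "right_facial")
})

test_that("a side-mixing facial module is flagged asymmetric", {
  fx <- facial_fixture()
  nodes2 <- c(fx$net$nodes, "zygomaticus_minor_R")
  meta2 <- rbind(fx$meta, toy_meta("zygomaticus_minor_R", tissue = "muscle",
                                   group = "hyoid", facial = TRUE))
  net2 <- anatomical_network(nodes2,
                             rbind(fx$net$edges, c("zygomaticus_minor_R", "maxilla_L")),
                             meta2, taxon_id = "toy")
  assign2 <- c(fx$assign, zygomaticus_minor_R = 0)
  pr <- profile_module(net2, as_partition(assign2, net2), 0)
  expect_equal(pr$label, "left_facial")
  expect_true(pr$asymmetric)
})

test_that("arytenoid cartilages plus their muscles form a vocal-fold module", {
  fx <- facial_fixture()
  part <- as_partition(fx$assign, fx$net)
  pr <- profile_module(fx$net, part, 2)
  expect_equal(pr$label, "true_vocal_fold_movement")
  expect_false(pr$asymmetric)
  expect_error(profile_module(fx$net, part, 99), "unknown module")
})

test_that("facial muscle counts partition across modules", {
  fx <- facial_fixture()
  part <- as_partition(fx$assign, fx$net)
  profs <- profile_modules(fx$net, part)
  expect_equal(sum(vapply(profs, function(p) p$facial_muscle_count, integer(1))),
               sum(fx$meta$is_facial_expression))
})

test_that("label assignment is a pure function of the module composition", {
  fx <- facial_fixture()
  part <- as_partition(fx$assign, fx$net)
  a <- vapply(profile_modules(fx$net, part), function(p) p$label, character(1))
  b <- vapply(profile_modules(fx$net, part), function(p) p$label, character(1))
  expect_identical(a, b)
  expect_true(all(a %in% module_labels()))
})

test_that("inclusion percentages reproduce printed fractions with half-up rounding", {
  expect_equal(facial_inclusion_percent(36, 48), 75)
  expect_equal(facial_inclusion_percent(29, 44), 66)
  expect_equal(facial_inclusion_percent(30, 44), 68)
  expect_equal(facial_inclusion_percent(33, 46), 72)
  expect_equal(facial_inclusion_percent(24, 38), 63)
  expect_equal(facial_inclusion_percent(22, 42), 52)
  expect_equal(facial_inclusion_percent(0, 48), 0)
  expect_error(facial_inclusion_percent(5, 0), "facial")
  expect_error(facial_inclusion_percent(49, 48), "exceeds")
})

test_that("facial inclusion counts muscles inside facial-labeled modules", {
  fx <- facial_fixture()
  part <- as_partition(fx$assign, fx$net)
  profs <- profile_modules(fx$net, part)
  fi <- facial_inclusion(part, fx$meta, profs, taxon_id = "toy")
  expect_equal(fi$n_in_facial, 6)
  expect_equal(fi$n_total_facial, 6)
  expect_equal(fi$percent, 100)
  no_facial <- toy_meta(fx$net$nodes)
  expect_error(facial_inclusion(part, no_facial, profs), "facial")
})

test_that("asymmetry report distinguishes the three facial configurations", {
  fx <- facial_fixture()
  part <- as_partition(fx$assign, fx$net)
  profs <- profile_modules(fx$net, part)
  rep0 <- asymmetry_report(profs, "plesiomorphic")
  expect_false(rep0$facial_modules_asymmetric)    # pure left + pure right
  expect_true(rep0$has_left_right_facial)
  expect_false(rep0$has_main_facial)

  # merge left and right facial nodes into one module: main facial pattern
  merged <- fx$assign
  merged[merged == 1] <- 0
  profs_m <- profile_modules(fx$net, as_partition(merged, fx$net))
  rep_m <- asymmetry_report(profs_m, "anthropoid")
  expect_true(rep_m$has_main_facial)
  expect_true(rep_m$facial_modules_asymmetric)
})

test_that("synthetic networks reproduce the expected asymmetry calls", {
  # mirror-symmetric anatomy: planted facial modules are side-pure
  gen <- generate_network(synthetic_spec(asymmetry_rate = 0, seed = 5))
  profs <- profile_modules(gen$network, gen$planted)
  expect_false(asymmetry_report(profs)$facial_modules_asymmetric)

  # cross-side attachments pull nodes of the opposite side into the
  # detected facial modules, the anthropoid-like pattern
  genA <- generate_network(synthetic_spec(asymmetry_rate = 0.15, seed = 7))
  detA <- detect_modules_greedy(genA$network)
  profsA <- profile_modules(genA$network, detA)
  expect_true(asymmetry_report(profsA)$facial_modules_asymmetric)
})
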