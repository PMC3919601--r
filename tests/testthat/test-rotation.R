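panel <- landmark_panel()
profiles <- default_state_profiles(panel)

profile_of <- function(name) {
  rotation_profile(name, profiles[[name]]$landmark_targets)
}

test_that("the default panel carries the bridge landmark annotations", {
  expect_equal(nrow(panel), 15)
  a2207 <- panel[panel$base_id == "A2207", ]
  expect_equal(a2207$ref_nonrotated, 2L)
  expect_equal(a2207$ref_rotated, 4L)
  expect_equal(a2207$region, "B7a")
  g2302 <- panel[panel$base_id == "G2302", ]
  expect_equal(g2302$ref_nonrotated, 0L)
  expect_equal(g2302$ref_rotated, 0L)
  expect_true(g2302$is_control)
  expect_equal(sum(informative_bases(panel)), 11)
  expect_setequal(unique(panel$region), c("B7a", "B2a", "B3", "AC", "SRL"))
})

test_that("reference columns score exactly at the continuum endpoints", {
  expect_equal(rotation_score(profile_of("non_rotated"), panel)$score, 0)
  expect_equal(rotation_score(profile_of("rotated"), panel)$score, 1)
})

test_that("mutant columns reproduce the hand-derived continuum positions", {
  a106r <- rotation_score(profile_of("A106R"), panel)
  s104d <- rotation_score(profile_of("S104D"), panel)
  expect_equal(a106r$score, 5 / 33)
  expect_equal(s104d$score, 10 / 11)
  expect_equal(a106r$n_informative, 11)
  expect_equal(classify_rotation(a106r), "non-rotated-shifted")
  expect_equal(classify_rotation(s104d), "rotated-shifted")
  expect_equal(classify_rotation(0.5), "intermediate")
})

test_that("missing bases are excluded and reported", {
  codes <- profiles$S104D$landmark_targets
  codes <- codes[!names(codes) %in% c("A2207", "G913")]
  sc <- rotation_score(rotation_profile("partial", codes), panel)
  expect_equal(sc$n_informative, 9)
  expect_setequal(sc$missing, c("A2207", "G913"))
  only_b3 <- rotation_profile("b3only", c(U2301 = 0L, G2302 = 0L))
  expect_error(rotation_score(only_b3, panel), "no informative")
})

test_that("moving any informative code toward rotated never lowers the score", {
  set.seed(33)
  info_ids <- panel$base_id[informative_bases(panel)]
  for (i in 1:50) {
    codes <- setNames(sample(0:4, nrow(panel), replace = TRUE),
                      panel$base_id)
    base_score <- rotation_score(rotation_profile("x", codes), panel)$score
    b <- sample(info_ids, 1)
    ref_rot <- panel$ref_rotated[panel$base_id == b]
    step <- sign(ref_rot - codes[b])
    if (step == 0) next
    codes[b] <- codes[b] + step
    expect_gte(rotation_score(rotation_profile("x", codes), panel)$score,
               base_score)
  }
})

test_that("B3 internal control flags large deviations", {
  s104d_b3 <- c(U2301 = 1L, G2302 = 0L, A1655 = 2L, U1656 = 2L)
  chk <- b3_control_check(rotation_profile("s104d", s104d_b3), panel)
  expect_true(chk$pass)
  expect_equal(chk$max_deviation, 1L)

  exact <- c(U2301 = 0L, G2302 = 0L, A1655 = 1L, U1656 = 2L)
  chk0 <- b3_control_check(rotation_profile("ref", exact), panel)
  expect_true(chk0$pass)
  expect_equal(chk0$max_deviation, 0L)

  bad <- c(U2301 = 3L, G2302 = 0L, A1655 = 1L, U1656 = 2L)
  expect_false(b3_control_check(rotation_profile("bad", bad), panel)$pass)
  expect_error(b3_control_check(rotation_profile("none", c(A2207 = 1L)),
                                panel), "B3")
})

test_that("difference maps subtract, bin in SD steps and are antisymmetric", {
  set.seed(5)
  trA <- random_trace(80)
  trB_raw <- tibble::tibble(position = 1:80, net = rlnorm(80, -1, 1))
  trB <- normalize_by_region_median(trB_raw)

  self <- difference_map(trA, trA)
  expect_true(all(self$delta == 0))
  expect_true(all(self$bin == 0L))

  ab <- difference_map(trA, trB)
  ba <- difference_map(trB, trA)
  expect_equal(ab$delta, -ba$delta)
  expect_equal(ab$bin, -ba$bin)

  # the stored bins satisfy the signed SD-step formula, evaluated directly
  s <- attr(ab, "sigma")
  expect_identical(ab$bin,
                   as.integer(sign(ab$delta) *
                                pmin(4, floor(abs(ab$delta) / s))))

  # shifting a trace by a known multiple of its own SD gives that SD step:
  # a constant shift leaves both SDs (hence the pooled sigma) unchanged
  sdA <- trace_statistics(trA)$sd
  for (case in list(c(1.5, 1), c(2.3, 2), c(0.4, 0), c(-1.5, -1))) {
    shifted <- trA
    shifted$reactivity <- trA$reactivity + case[1] * sdA
    shifted <- riborotate:::new_normalized_trace(shifted)
    expect_true(all(difference_map(shifted, trA)$bin == as.integer(case[2])))
  }
  expect_error(difference_map(trA, random_trace(50)), "identical positions")
})

test_that("landmark codes assemble into profiles by subunit and position", {
  ct <- tibble::tibble(subunit = c("25S", "18S"), position = c(2207L, 913L),
                       code = c(4L, 4L))
  prof <- codes_to_profile(ct, panel, "demo")
  expect_equal(unname(prof$codes[c("A2207", "G913")]), c(4L, 4L))
  expect_true(all(is.na(prof$codes[setdiff(panel$base_id,
                                           c("A2207", "G913"))])))
})
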