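# All phantom tests run on a coarse 4 mm / 48^3 grid: the geometry is
# identical in mm, only the sampling is coarser, which keeps the Monte-Carlo
# style checks fast.

test_that("phantom construction: nesting, determinism, plausible volumes", {
  cfg <- test_phantom_config()
  set <- generate_phantom(cfg)
  expect_true(all(c("Brain", "GTV", "BTV", "GTVu", "PTV75", "PTV60ex", "PTV60",
                    "Brainstem", "OpticChiasm", "Pituitary") %in% names(set$masks)))

  gtvu <- get_structure(set, "GTVu")$occupancy
  ptv75 <- get_structure(set, "PTV75")$occupancy
  ptv60ex <- get_structure(set, "PTV60ex")$occupancy
  ptv60 <- get_structure(set, "PTV60")$occupancy
  expect_true(all(!gtvu | ptv75))      # GTVu strictly inside PTV75
  expect_true(all(!ptv75 | ptv60ex))
  expect_true(all(!ptv75 | ptv60))
  expect_gt(sum(ptv75), sum(gtvu))
  expect_gt(sum(ptv60ex), sum(ptv75))

  set2 <- generate_phantom(cfg)
  expect_identical(get_structure(set2, "GTVu")$occupancy, gtvu)

  # default-scale phantom volumes land in the clinically plausible band
  full <- generate_phantom(phantom_config())
  v60 <- volume_cc(get_structure(full, "PTV60"))
  expect_gt(v60, 100); expect_lt(v60, 500)
  vu <- volume_cc(get_structure(full, "GTVu"))
  expect_gt(vu, 10); expect_lt(vu, 120)

  bad <- phantom_config(spacing = c(4, 4, 4), shape = c(20, 20, 20))
  expect_error(generate_phantom(bad), class = "planqa_parameter_error")
})

test_that("PET simulation and TBR threshold segmentation", {
  cfg <- test_phantom_config()
  set <- generate_phantom(cfg)
  pet <- simulate_pet(set, background_uptake = 1, lesion_tbr = 2.5, noise_sd = 0)
  brain <- get_structure(set, "Brain")
  btv <- get_structure(set, "BTV")
  bg_vox <- brain$occupancy & !btv$occupancy
  expect_equal(unique(pet$uptake[btv$occupancy]) / unique(pet$uptake[bg_vox]), 2.5)

  pet_a <- simulate_pet(set, noise_sd = 0.1, seed = 7)
  pet_b <- simulate_pet(set, noise_sd = 0.1, seed = 7)
  expect_identical(pet_a$uptake, pet_b$uptake)
  pet_c <- simulate_pet(set, noise_sd = 0.1, seed = 8)
  expect_false(identical(pet_a$uptake, pet_c$uptake))

  # noise-free threshold at 1.8 on a TBR 2.5 lesion recovers the lesion,
  # using normal brain away from the lesion as the background region
  bg_region <- mask_difference(brain, dilate_mask(btv, 8), name = "bg")
  rec <- btv_from_pet(pet, bg_region, 1.8)
  expect_identical(rec$occupancy, btv$occupancy)

  high <- btv_from_pet(pet, bg_region, 3.5)
  expect_false(any(high$occupancy))

  # lowering the threshold can only grow the BTV (1.8 -> 1.6 trial change)
  noisy <- simulate_pet(set, noise_sd = 0.15, seed = 3)
  b18 <- btv_from_pet(noisy, bg_region, 1.8)
  b16 <- btv_from_pet(noisy, bg_region, 1.6)
  expect_true(all(!b18$occupancy | b16$occupancy))

  expect_error(simulate_pet(set, lesion_tbr = 1), class = "planqa_parameter_error")
  empty <- structure_mask("E", set$geometry, array(FALSE, set$geometry$shape), "oar")
  expect_error(btv_from_pet(pet, empty), class = "planqa_empty_mask")
})

test_that("dose simulation: target medians, falloff, OAR proximity effect", {
  cfg <- test_phantom_config()
  set <- generate_phantom(cfg)
  dc0 <- dose_model_config(noise_sd = 0)

  d_std <- simulate_dose(set, dc0, "standard", seed = 1)
  dvh60 <- cumulative_dvh(d_std, get_structure(set, "PTV60"))
  expect_equal(dose_at_relative_volume(dvh60, 50, method = "exact"), 60, tolerance = 0.6)

  d_exp <- simulate_dose(set, dc0, "experimental", seed = 1)
  dvh75 <- cumulative_dvh(d_exp, get_structure(set, "PTV75"))
  expect_equal(dose_at_relative_volume(dvh75, 50, method = "exact"), 75, tolerance = 0.75)

  # dose is nonincreasing with distance outside the outermost target
  ptv60 <- get_structure(set, "PTV60")
  shells <- lapply(c(0, 4, 8, 12), function(m) {
    out <- dilate_mask(ptv60, m + 4)$occupancy & !dilate_mask(ptv60, m)$occupancy
    mean(d_std$dose[out])
  })
  expect_true(all(diff(unlist(shells)) < 0))

  # moving the brainstem closer to the target raises its D0.03cc
  far_dvh <- cumulative_dvh(d_std, get_structure(set, "Brainstem"))
  near_cfg <- test_phantom_config()
  near_cfg$oars$Brainstem$center_xy <- near_cfg$brain_center[1:2] + c(10, 0)
  near_set <- generate_phantom(near_cfg)
  d_near <- simulate_dose(near_set, dc0, "standard", seed = 1)
  near_dvh <- cumulative_dvh(d_near, get_structure(near_set, "Brainstem"))
  expect_gt(dose_at_absolute_volume(near_dvh, 0.03),
            dose_at_absolute_volume(far_dvh, 0.03))

  expect_error(simulate_dose(structure_set(set$geometry, list(get_structure(set, "Brain"))),
                             dc0, "standard"),
               class = "planqa_missing_structure")

  # seeded noise is reproducible
  dcn <- dose_model_config(noise_sd = 0.3)
  expect_identical(simulate_dose(set, dcn, "standard", seed = 4)$dose,
                   simulate_dose(set, dcn, "standard", seed = 4)$dose)
})

test_that("center submissions: identity at zero profile, seeded reproducibility", {
  ref <- simulate_reference_bundle(test_phantom_config(),
                                   dose_model_config(noise_sd = 0),
                                   "experimental", seed = 2)
  zero <- perturbation_profile(translation_sd = 0, boundary_sd = 0)
  sub0 <- generate_center_submission(ref, zero, seed = 9)
  for (nm in c("GTVu", "PTV75", "Brainstem")) {
    expect_identical(get_structure(sub0$structures, nm)$occupancy,
                     get_structure(ref$structures, nm)$occupancy)
  }
  expect_equal(dice(get_structure(sub0$structures, "GTVu"),
                    get_structure(ref$structures, "GTVu")), 1)

  prof <- perturbation_profile(translation_sd = 3, boundary_sd = 2)
  s1 <- generate_center_submission(ref, prof, seed = 5)
  s2 <- generate_center_submission(ref, prof, seed = 5)
  expect_identical(get_structure(s1$structures, "GTVu")$occupancy,
                   get_structure(s2$structures, "GTVu")$occupancy)
  s3 <- generate_center_submission(ref, prof, seed = 6)
  expect_false(identical(get_structure(s1$structures, "GTVu")$occupancy,
                         get_structure(s3$structures, "GTVu")$occupancy))
  # perturbed submissions stay plausible: DSC in (0,1), HD > 0
  cmp <- tidy(compare_structure_sets(ref$structures, s1$structures,
                                     structures = c("GTVu", "PTV75")))
  expect_true(all(cmp$dsc > 0 & cmp$dsc < 1))
  expect_true(all(cmp$hd_mm > 0))
})

test_that("median DSC decreases and HD increases with translation noise", {
  ref <- simulate_reference_bundle(test_phantom_config(),
                                   dose_model_config(noise_sd = 0),
                                   "experimental", seed = 2)
  sds <- c(1, 3, 6)
  med_dsc <- med_hd <- numeric(length(sds))
  for (i in seq_along(sds)) {
    prof <- perturbation_profile(translation_sd = sds[i], boundary_sd = 0)
    res <- vapply(1:20, function(s) {
      sub <- generate_center_submission(ref, prof, seed = s)
      c(dice(get_structure(ref$structures, "GTVu"),
             get_structure(sub$structures, "GTVu")),
        hausdorff(get_structure(ref$structures, "GTVu"),
                  get_structure(sub$structures, "GTVu")))
    }, numeric(2))
    med_dsc[i] <- median(res[1, ])
    med_hd[i] <- median(res[2, ])
  }
  expect_true(all(diff(med_dsc) < 0))
  expect_true(all(diff(med_hd) > 0))
})

test_that("edema-inclusion override inflates GTVu and trips the volume check", {
  ref <- simulate_reference_bundle(test_phantom_config(),
                                   dose_model_config(noise_sd = 0),
                                   "experimental", seed = 2)
  v_ref <- volume_cc(get_structure(ref$structures, "GTVu"))
  prof <- perturbation_profile(translation_sd = 0, boundary_sd = 0,
                               overrides = list(GTV = list(dilate_mm = 8)))
  edema <- generate_center_submission(ref, prof, seed = 1, center_label = "edema")
  v_edema <- volume_cc(get_structure(edema$structures, "GTVu"))
  expect_gt(v_edema / v_ref, 1.7)  # roughly doubled

  rule <- constraint_rule("GTVu", "V0Gy", "<=", v_ref * 1.3, scope = "experimental")
  expect_equal(as.character(evaluate_constraint(edema, rule)$classification), "deviation")
  expect_equal(as.character(evaluate_constraint(ref, rule)$classification), "within_protocol")
})
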