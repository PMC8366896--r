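test_that("available protein is 6.25 times the unbound nitrogen", {
  # Betula pendula: CP 8.8 => total N 1.408; AP 5.7 => ADF-N 0.496
  expect_equal(available_protein(1.408, 0.496), 5.7)
  expect_equal(available_protein(2, 0), 12.5)
  expect_equal(available_protein(1, 1), 0)
  # linear and homogeneous in (total_n - adf_n)
  d <- c(0.3, 1.7, 2.2)
  expect_equal(available_protein(3 * d, 2 * d), 6.25 * d)
  expect_error(available_protein(1, 1.2, sample_id = "X1"), "X1")
})

test_that("fiber fractions follow the detergent ladder", {
  expect_equal(fiber_fractions(50, 30, 10),
               data.frame(hemicellulose = 20, cellulose = 20))
  expect_equal(fiber_fractions(15, 15, 15),
               data.frame(hemicellulose = 0, cellulose = 0))
  # Pinus sylvestris: adf = lignin + cellulose = 9.5 + 25.6
  expect_equal(fiber_fractions(43.1, 35.1, 9.5),
               data.frame(hemicellulose = 8.0, cellulose = 25.6))
  expect_error(fiber_fractions(30, 50, 10), "ordering")
})

test_that("TNC2+lipids closes the composition and clips small deficits", {
  expect_equal(tnc2_lipids(50, 20, 5), 25)
  expect_equal(tnc2_lipids(100, 0, 0), 0)
  expect_equal(tnc2_lipids(46, 14, 6), 34)
  expect_warning(out <- tnc2_lipids(60, 35, 5.3), "clipped")
  expect_equal(out, 0)
  expect_error(tnc2_lipids(60, 40, 5), "exceeds 100")
})

test_that("TNC1 and microbial N conversions", {
  expect_equal(tnc1(0, 0), 0)
  expect_equal(tnc1(60, 14), 74)
  expect_equal(tnc1(10.1, 0), 10.1)
  expect_error(tnc1(-1, 0))
  expect_equal(microbial_n(0), 0)
  expect_equal(microbial_n(1), 1.1)
  expect_equal(microbial_n(0.836), 0.9196)
  expect_error(microbial_n(-0.1))
})

test_that("derived rumen profiles satisfy exact closure", {
  prof <- derive_profiles(toy_records(), "rumen")
  expect_equal(nrow(prof), 3)
  expect_closure(prof, tol = 1e-12)
  a <- prof[prof$sample_id == "A", ]
  expect_equal(a$ap, 20)
  expect_equal(a$hemicellulose, 20)
  expect_equal(a$cellulose, 20)
  expect_equal(a$fiber, 40)
  expect_equal(a$tnc2_lipids, 25)
  expect_equal(a$microbial_n, 0.55)
  expect_equal(nrow(validation_report(prof)), 0)
})

test_that("degenerate all-zero chemistry yields pure TNC2", {
  rec <- data.frame(sample_id = "Z", ash = 0, total_n = 0, adf_n = 0,
                    ndf = 0, adf = 0, lignin = 0)
  prof <- derive_profiles(rec, "rumen")
  expect_equal(prof$tnc2_lipids, 100)
  expect_equal(prof$ap + prof$fiber + prof$ash, 0)
})

test_that("plant profiles use the enzymatic TNC path", {
  rec <- data.frame(sample_id = "P", ash = 3, total_n = 1.408,
                    adf_n = 0.496, ndf = 57.7, adf = 48, lignin = 18.1,
                    sugars = 4, starch = 1.7, lipids = 4.0)
  prof <- derive_profiles(rec, "plant")
  expect_equal(prof$ap, 5.7)
  expect_equal(prof$crude_protein, 8.8)
  expect_equal(prof$tnc1, 5.7)
  expect_equal(prof$lipids, 4.0)
  expect_false("tnc2_lipids" %in% names(prof))
})

test_that("invalid records are rejected with named reasons, others kept", {
  bad <- rbind(toy_records(),
               data.frame(sample_id = c("D", "E"),
                          ash = c(5, 120), total_n = c(1, 1),
                          adf_n = c(2, 0), ndf = c(50, 40),
                          adf = c(30, 30), lignin = c(10, 10),
                          purine_marker = c(0, 0)))
  expect_warning(prof <- derive_profiles(bad, "rumen"), "rejected")
  expect_equal(prof$sample_id, c("A", "B", "C"))
  rep <- validation_report(prof)
  expect_setequal(rep$sample_id, c("D", "E"))
  expect_true(all(rep$action == "rejected"))
})

test_that("monotonicity: TNC2+lipids decreases in each closure input", {
  base <- tnc2_lipids(50, 20, 5)
  eps <- 0.7
  expect_lt(tnc2_lipids(50 + eps, 20, 5), base)
  expect_lt(tnc2_lipids(50, 20 + eps, 5), base)
  expect_lt(tnc2_lipids(50, 20, 5 + eps), base)
})

test_that("CSV round trip and decimal-comma rejection", {
  path <- tempfile(fileext = ".csv")
  write.csv(toy_records(), path, row.names = FALSE)
  back <- read_proximate_csv(path)
  expect_equal(back$ndf, toy_records()$ndf)

  bad <- tempfile(fileext = ".csv")
  writeLines(c("sample_id,ash,total_n,adf_n,ndf,adf,lignin",
               'S1,"5,3",1,0,50,30,10'), bad)
  expect_error(read_proximate_csv(bad), "decimal commas")
})
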