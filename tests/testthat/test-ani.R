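# Fragment ANI and the species-assignment rule.

test_that("self-comparison gives ANI 100, AF 1", {
  for (len in c(2500L, 10000L, 10400L)) {   # incl. shorter-than-fragment
    g <- random_genome(len, len)
    a <- fragment_ani(g, g)
    expect_equal(a$ani_pct, 100)
    expect_equal(a$align_frac, 1)
  }
})

test_that("ANI tracks 100*(1-rate) for seeded mutations", {
  g <- random_genome(11, 60000)
  rates <- c(0.01, 0.03, 0.05, 0.10)
  est <- vapply(seq_along(rates), function(i) {
    m <- mutate_genome(g, rates[i], seed = 100 + i)
    a <- fragment_ani(m, g)
    expect_gt(a$align_frac, 0.5)
    a$ani_pct
  }, numeric(1))
  expect_true(all(abs(est - 100 * (1 - rates)) < 0.5))
  expect_true(all(diff(est) < 0))
})

test_that("reverse-complemented genomes still align", {
  g <- random_genome(21, 30000)
  rc <- paste(rev(strsplit(chartr("ACGT", "TGCA", g), "")[[1]]),
              collapse = "")
  a <- fragment_ani(rc, g)
  expect_equal(a$ani_pct, 100)
  expect_equal(a$align_frac, 1)
})

test_that("unrelated sequences produce no alignment", {
  a <- fragment_ani(random_genome(1, 30000), random_genome(2, 30000))
  # expected seed collisions ~ L^2 / 4^16 << 1 per fragment
  expect_lt(a$align_frac, 0.05)
})

test_that("fragmenting rules: partials dropped, short genomes truncated", {
  g <- random_genome(5, 7500)          # 2 full fragments + 1500 partial
  a <- fragment_ani(g, g)
  expect_equal(a$n_fragments, 2L)
  short <- fragment_ani(substr(g, 1, 1200), g)
  expect_equal(short$n_fragments, 1L)
  expect_match(paste(short$warnings, collapse = " "), "truncated")
  expect_equal(short$ani_pct, 100)
  expect_error(fragment_ani("", g), class = "taxoplace_validation_error")
  expect_error(fragment_ani(g, g, k = 16, fragment_len = 100),
               class = "taxoplace_validation_error")
})

radii_fix <- data.frame(
  species_name = c("s__Saureus", "s__Sepidermidis"),
  representative_genome = c("RS_aureus", "RS_epi"),
  radius_pct = c(95, 95), stringsAsFactors = FALSE)

ani_res <- function(ref, ani, af) {
  structure(list(reference = ref, ani_pct = ani, align_frac = af,
                 n_fragments = 10L, warnings = character()),
            class = "ani_result")
}

test_that("species_assign applies radius (inclusive) and AF (strict)", {
  r <- species_assign(list(ani_res("RS_aureus", 97.1, 0.82)), radii_fix)
  expect_equal(r$species, "s__Saureus")

  r2 <- species_assign(list(ani_res("RS_aureus", 94.2, 0.82)), radii_fix)
  expect_true(is.na(r2$species))

  r3 <- species_assign(list(ani_res("RS_aureus", 99.0, 0.60)), radii_fix)
  expect_true(is.na(r3$species))
  # af exactly at the threshold fails (strict >)
  r4 <- species_assign(list(ani_res("RS_aureus", 99.0, 0.65)), radii_fix)
  expect_true(is.na(r4$species))
  # ani exactly at the radius passes (inclusive >=)
  r5 <- species_assign(list(ani_res("RS_aureus", 95.0, 0.80)), radii_fix)
  expect_equal(r5$species, "s__Saureus")

  expect_true(is.na(species_assign(list(), radii_fix)$species))
})

test_that("species_assign picks highest ANI; ties go alphabetically", {
  r <- species_assign(list(ani_res("RS_epi", 98.0, 0.8),
                           ani_res("RS_aureus", 96.0, 0.9)), radii_fix)
  expect_equal(r$species, "s__Sepidermidis")
  tie <- species_assign(list(ani_res("RS_epi", 98.0, 0.8),
                             ani_res("RS_aureus", 98.0, 0.9)), radii_fix)
  expect_equal(tie$species, "s__Saureus")
  expect_match(paste(tie$warnings, collapse = " "), "tie")
})

test_that("unknown representatives fall back to the default radius", {
  r <- species_assign(list(ani_res("RS_mystery", 96.0, 0.9)), radii_fix,
                      default_radius = 95)
  expect_true(is.na(r$species))   # no species name known -> no assignment
  expect_match(paste(r$warnings, collapse = " "), "default radius")
})
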