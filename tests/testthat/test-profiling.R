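test_that("residue profiles accumulate overlapping peptide weight", {
  cas <- bundled_caseins()
  beta <- cas$CASB_BOVIN

  one <- make_obs("YPFPGPI", intensity = 5, protein_id = "CASB_BOVIN",
                  start = 60L, end = 66L)
  pr <- residue_profile(one, beta, "intensity_sum")
  expect_length(pr$values, 209L)
  expect_equal(pr$values[60:66], rep(5, 7))
  expect_equal(sum(pr$values), 5 * 7)

  two <- rbind(
    make_obs("X", intensity = 2, protein_id = "CASB_BOVIN", start = 10L, end = 20L),
    make_obs("X", intensity = 3, protein_id = "CASB_BOVIN", start = 15L, end = 25L))
  pr2 <- residue_profile(two, beta, "intensity_sum")
  expect_equal(pr2$values[10:14], rep(2, 5))
  expect_equal(pr2$values[15:20], rep(5, 6))
  expect_equal(pr2$values[21:25], rep(3, 5))
  expect_equal(pr2$values[c(5, 30)], c(0, 0))

  # occurrence mode ignores intensity; equals intensity mode at weight 1
  oc <- residue_profile(two, beta, "occurrence_count")
  two1 <- two; two1$intensity <- 1
  expect_equal(oc$values, residue_profile(two1, beta, "intensity_sum")$values)
  expect_true(all(oc$values == floor(oc$values)))

  bad <- make_obs("X", protein_id = "CASB_BOVIN", start = 200L, end = 215L)
  expect_error(residue_profile(bad, beta), "bounds")
})

test_that("profile totals conserve intensity x length on simulated peptidomes", {
  cas <- bundled_caseins()
  for (seed in c(3, 11, 29)) {
    sim <- simulate_digest(small_digest_config(seed))
    mapped <- truth_as_mapped(sim)
    total <- 0
    for (p in cas) {
      total <- total + sum(residue_profile(mapped, p, "intensity_sum")$values)
    }
    expect_equal(total, sum(mapped$intensity * nchar(mapped$sequence)))
    occ <- sum(vapply(cas, function(p)
      sum(residue_profile(mapped, p, "occurrence_count")$values), 0))
    expect_equal(occ, sum(nchar(mapped$sequence)))
  }
})

test_that("profile_matrix rows equal per-sample residue profiles", {
  beta <- bundled_caseins()$CASB_BOVIN
  obs <- rbind(
    make_obs("A", intensity = 2, substrate = "casein", time_min = 5L,
             protein_id = "CASB_BOVIN", start = 1L, end = 10L),
    make_obs("B", intensity = 3, substrate = "hydrolysate", time_min = 30L,
             protein_id = "CASB_BOVIN", start = 100L, end = 120L))
  m <- profile_matrix(obs, beta, "intensity_sum")
  expect_equal(dim(m), c(2L, 209L))
  expect_equal(rownames(m), c("casein@5", "hydrolysate@30"))
  # disjoint peptides give a block structure with zero cross-terms
  expect_equal(unname(m["casein@5", 100:120]), rep(0, 21))
  expect_equal(unname(m["hydrolysate@30", 1:10]), rep(0, 10))
  pr <- residue_profile(obs, beta, "intensity_sum",
                        sample_key = list(substrate = "casein", time_min = 5L))
  expect_equal(unname(m["casein@5", ]), pr$values)

  mn <- profile_matrix(obs, beta, "intensity_sum", normalize = TRUE)
  expect_equal(unname(rowSums(mn)), c(1, 1))
})

test_that("size distributions bin unique sequences with percentages", {
  obs <- make_obs(c("ACD", "ACDEFGH", "PQRSTVW", "ACDEFGHIKLMN"))
  sd_ <- size_distribution(obs)
  expect_equal(sd_$count, c(1L, 2L, 1L, 0L))
  expect_equal(sd_$percent, c(25, 50, 25, 0))
  expect_equal(sum(sd_$percent), 100)

  # duplicated sequences count once; grouping by substrate splits totals
  obs2 <- rbind(obs, make_obs("ACDEFGH", substrate = "hydrolysate"))
  sd2 <- size_distribution(obs2)
  expect_equal(sd2$count[sd2$substrate == "hydrolysate"], c(0L, 1L, 0L, 0L))
  expect_equal(sd2$percent[sd2$substrate == "hydrolysate"], c(0, 100, 0, 0))
  expect_equal(sd2$count[sd2$substrate == "casein"], c(1L, 2L, 1L, 0L))

  expect_equal(nrow(size_distribution(obs[0, ])), 0L)
  expect_error(size_distribution(obs, bin_edges = c(2, 2, 10)), "increasing")
})

test_that("count summaries follow the printed-table arithmetic", {
  # 2 animals: X seen by both, Y by one -> total 2, common 1
  obs <- rbind(make_obs(c("AAAAA", "CCCCC"), animal_id = "pig1"),
               make_obs("AAAAA", animal_id = "pig2"))
  cs <- count_summary(obs, n_animals = 2L)
  expect_equal(cs$per_time$total, 2L)
  expect_equal(cs$per_time$common, 1L)
  expect_error(count_summary(obs, 0), "n_animals")

  # random presence structure vs explicit set operations
  set.seed(9)
  pool <- random_peptides(30)
  rows <- list()
  for (t in c(5L, 30L)) for (a in paste0("pig", 1:3)) {
    rows[[length(rows) + 1L]] <- make_obs(sample(pool, 12), time_min = t,
                                          animal_id = a)
  }
  obs2 <- do.call(rbind, rows)
  cs2 <- count_summary(obs2, 3L)
  for (t in c(5L, 30L)) {
    sets <- lapply(paste0("pig", 1:3), function(a)
      unique(obs2$sequence[obs2$time_min == t & obs2$animal_id == a]))
    expect_equal(cs2$per_time$total[cs2$per_time$time_min == t],
                 length(unique(unlist(sets))))
    expect_equal(cs2$per_time$common[cs2$per_time$time_min == t],
                 length(Reduce(intersect, sets)))
  }
  # column totals are sums over time points
  expect_equal(cs2$column_totals$total, sum(cs2$per_time$total))

  # common <= total everywhere; totals monotone under added observations
  expect_true(all(cs2$per_time$common <= cs2$per_time$total))
  more <- rbind(obs2, make_obs("WWWWWW", time_min = 5L))
  cs3 <- count_summary(more, 3L)
  expect_true(all(cs3$per_time$total >= cs2$per_time$total))

  # deduplicated union is a different (smaller or equal) quantity
  expect_lte(dedup_union(obs2)$unique_sequences, cs2$column_totals$total)
})
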