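test_that("the junction fragment spans the nearest cut sites", {
  # one AluI site at 0-based offset 80 and one RsaI site at 150, junction at
  # 100: mid-site cuts at 82 and 152, fragment [82, 152)
  s <- strrep("A", 200)
  substr(s, 81, 84) <- "AGCT"
  substr(s, 151, 154) <- "GTAC"
  fr <- junctionFragment(s, 100, c("AGCT", "GTAC"))
  expect_true(fr$found)
  expect_identical(fr$start, 82L)
  expect_identical(fr$end, 152L)
  # no cut site within the cap on one side: unrecoverable
  expect_false(junctionFragment(s, 100, c("AGCT", "GTAC"),
                                maxFragment = 40L)$found)
})

test_that("fragment boundaries agree with a brute-force cut-site scan", {
  set.seed(33)
  for (i in 1:100) {
    s <- randomSeq(sample(300:1200, 1))
    j <- sample(50:(nchar(s) - 50), 1)
    enz <- sample(c("AGCT", "GGCC", "GTAC"), sample(1:2, 1))
    a <- junctionFragment(s, j, enz, maxFragment = 400L)
    b <- bruteFragment(s, j, enz, maxFragment = 400L)
    expect_identical(a$found, b$found)
    if (a$found) {
      expect_identical(a$start, b$start)
      expect_identical(a$end, b$end)
    }
  }
})

test_that("short flanks are dropped and tallies reconcile with planted events", {
  cfg <- tinyConfig()
  sim <- tinySim()
  dg <- digestEvents(sim$genome, sim$events, "L1Hs", cfg)
  t <- dg$tallies
  expect_identical(unname(t[["planted"]]),
                   length(insertionEvents(sim$events)))
  expect_identical(t[["planted"]],
                   t[["amplifiable"]] + t[["suppression_loss"]] +
                     t[["short_flank"]] + t[["primer_loss"]])
  expect_true(all(dg$fragments$flank_len >= cfg@minFlank))
  # every amplifiable fragment corresponds to exactly one truth event
  expect_false(anyDuplicated(dg$fragments$event_id) > 0)
  expect_true(all(dg$fragments$event_id %in%
                    insertionEvents(sim$events)$event_id))
})

test_that("raising the flank minimum drops borderline fragments", {
  cfg <- tinyConfig()
  sim <- tinySim()
  base <- digestEvents(sim$genome, sim$events, "L1Hs", cfg)
  cfg2 <- cfg
  cfg2@minFlank <- 60L
  strict <- digestEvents(sim$genome, sim$events, "L1Hs", cfg2)
  expect_true(all(strict$fragments$flank_len >= 60L))
  expect_lt(nrow(strict$fragments), nrow(base$fragments))
  gone <- setdiff(base$fragments$event_id, strict$fragments$event_id)
  lost <- base$fragments[base$fragments$event_id %in% gone, ]
  expect_true(all(lost$flank_len < 60L))
})
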