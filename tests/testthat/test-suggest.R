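# indicator table over tiny_kb with hand-set scores
tiny_table <- function(extra = NULL) {
  entries <- rbind(
    data.frame(item_id = c("I-001", "I-002", "I-003", "I-004"),
               dx_code = "DX-001",
               element_id = sprintf("DX-001-DC%02d", 1:4),
               score = c(0.95, 0.90, 0.85, 0.60),
               level = c("major", "major", "major", "minor"),
               stringsAsFactors = FALSE),
    data.frame(item_id = c("I-001", "I-002"),
               dx_code = "DX-002",
               element_id = sprintf("DX-002-DC%02d", 1:2),
               score = c(0.70, 0.40),
               level = c("minor", "excluded"),
               stringsAsFactors = FALSE),
    extra)
  indicator_table(entries, engine = "cdv")
}

findings_for <- function(items, present = TRUE, patient = "P-01") {
  data.frame(patient_id = patient, item_id = items,
             present = as.integer(present), stringsAsFactors = FALSE)
}

test_that("a diagnosis hit by three major elements is ranked first", {
  kb <- tiny_kb()
  g <- generate_guidance(findings_for(sprintf("I-%03d", 1:3)), tiny_table(),
                         kb)
  expect_s3_class(g, "guidance_list")
  expect_equal(g$ranking$dx_code[1], "DX-001")
  expect_gte(g$ranking$n_major[1], 3L)
  # excluded entries never surface
  expect_false("DX-002-DC02" %in% g$entries$element_id)
})

test_that("no positive findings produce empty guidance", {
  g <- generate_guidance(findings_for("I-001", present = FALSE),
                         tiny_table(), tiny_kb())
  expect_equal(nrow(g$entries), 0L)
  expect_equal(nrow(g$ranking), 0L)
})

test_that("exact ranking ties break lexicographically by diagnosis code", {
  # DX-001 and DX-002 get identical (major count, score sum) profiles
  entries <- data.frame(
    item_id = c("I-001", "I-003"),
    dx_code = c("DX-002", "DX-001"),
    element_id = c("DX-002-DC01", "DX-001-DC01"),
    score = c(0.9, 0.9), level = "major", stringsAsFactors = FALSE)
  tab <- indicator_table(entries, engine = "cdv")
  g <- generate_guidance(findings_for(c("I-001", "I-003")), tab, tiny_kb())
  expect_equal(g$ranking$dx_code, c("DX-001", "DX-002"))
})

test_that("guidance is a pure function of its inputs", {
  kb <- tiny_kb()
  f <- findings_for(sprintf("I-%03d", c(1, 3)))
  g1 <- generate_guidance(f, tiny_table(), kb)
  g2 <- generate_guidance(f, tiny_table(), kb)
  expect_identical(serialize(g1, NULL), serialize(g2, NULL))
})

test_that("adding a positive finding only accumulates guidance", {
  kb <- tiny_kb()
  tab <- tiny_table()
  base_items <- c("I-001", "I-002")
  g_small <- generate_guidance(findings_for(base_items), tab, kb)
  g_big <- generate_guidance(findings_for(c(base_items, "I-004")), tab, kb)
  for (dx in g_small$ranking$dx_code) {
    small_el <- g_small$entries$element_id[g_small$entries$dx_code == dx]
    big_el <- g_big$entries$element_id[g_big$entries$dx_code == dx]
    expect_true(all(small_el %in% big_el))
  }
})

test_that("every suggested element traces back to a positive finding", {
  kb <- tiny_kb()
  tab <- tiny_table()
  items <- c("I-001", "I-004")
  g <- generate_guidance(findings_for(items), tab, kb)
  for (i in seq_len(nrow(g$entries))) {
    src <- tab$entries$item_id[
      tab$entries$dx_code == g$entries$dx_code[i] &
        tab$entries$element_id == g$entries$element_id[i]]
    expect_true(any(src %in% items))
  }
})

test_that("duplicate element evidence keeps the maximum score", {
  # same element reachable from two items with different scores
  entries <- data.frame(
    item_id = c("I-001", "I-002"), dx_code = "DX-001",
    element_id = "DX-001-DC01", score = c(0.6, 0.9),
    level = c("minor", "major"), stringsAsFactors = FALSE)
  tab <- indicator_table(entries, engine = "cdv")
  g <- generate_guidance(findings_for(c("I-001", "I-002")), tab, tiny_kb())
  expect_equal(nrow(g$entries), 1L)
  expect_equal(g$entries$score, 0.9)
})

test_that("the control-arm engine lists taxonomy elements unscored", {
  kb <- tiny_kb()
  g <- null_guidance(findings_for("I-001"), kb)
  expect_equal(g$engine, "none")
  expect_true(all(is.na(g$entries$score)))
  # taxonomy order within each diagnosis
  for (dx in unique(g$entries$dx_code)) {
    expect_equal(g$entries$element_id[g$entries$dx_code == dx],
                 kb_diagnosis(kb, dx)$elements$element_id)
  }
})

test_that("the compliance rule needs three distinct taxonomy-valid elements", {
  kb <- tiny_kb()
  expect_true(adequately_supported(
    plan_row(elements = sprintf("DX-001-DC%02d", 1:3)), kb))
  # 2 valid + 1 out-of-taxonomy element is not enough
  expect_false(adequately_supported(
    plan_row(elements = c("DX-001-DC01", "DX-001-DC02", "BOGUS")), kb))
  # related factors do not count toward the rule
  expect_false(adequately_supported(
    plan_row(elements = c("DX-001-DC01", "DX-001-DC02", "DX-001-RF01")), kb))
  # risk diagnosis: risk factors count
  expect_true(adequately_supported(
    plan_row(dx = "DX-003", elements = sprintf("DX-003-RK%02d", 1:3)), kb))
  # duplicates are not distinct
  expect_false(adequately_supported(
    plan_row(elements = rep("DX-001-DC01", 3)), kb))
})
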