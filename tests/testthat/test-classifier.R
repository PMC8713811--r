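test_that("a b2m-signature Ig domain scores 1.0 for B2M", {
  ch <- make_chain("B2M", sim_config(seed = 1L), SCHEMA)
  hit <- map_to_frame(ch$sequence, SCHEMA$frames$IG_C1)
  scores <- score_domain(hit, ch$sequence, SCHEMA)
  expect_equal(unname(scores["B2M"]), 1.0)
  # the class I alpha3 diagnostics (P57, G61) are absent
  expect_equal(unname(scores["I_HEAVY"]), 0)
  # W61 alone also satisfies IIB's sole Ig diagnostic; that tie is resolved
  # by architecture gating and TM evidence in classify_chain, not here
  expect_gte(scores["B2M"], scores["IIB"])
})

test_that("domain scores equal exhaustive enumeration on a toy two-class frame", {
  # two classes over a 10-column frame: X wants (3 in {W,F}, 7 in {K});
  # Y wants (3 in {K}, 7 in {W}), weights 2 and 1
  toy <- schema_from_list(toy_schema_list(list(
    toy_sig(3L, "WF", "WA", weight = 2), toy_sig(7L, "K", "WA", weight = 1),
    toy_sig(3L, "K", "WB", weight = 2), toy_sig(7L, "W", "WB", weight = 1))))
  fr <- toy$frames$IG_C1
  hit <- map_to_frame(fr$consensus, fr)  # identity map, reused for all variants
  residues <- c("W", "F", "K", "A")
  cons <- strsplit(fr$consensus, "")[[1]]
  for (r3 in residues) {
    for (r7 in residues) {
      v <- cons; v[3L] <- r3; v[7L] <- r7
      got <- score_domain(hit, paste(v, collapse = ""), toy)
      exp_x <- (2 * (r3 %in% c("W", "F")) + 1 * (r7 == "K")) / 3
      exp_y <- (2 * (r3 == "K") + 1 * (r7 == "W")) / 3
      expect_equal(unname(got["WA"]), exp_x, info = paste(r3, r7))
      expect_equal(unname(got["WB"]), exp_y, info = paste(r3, r7))
    }
  }
})

test_that("fully gapped signature columns are flagged as zero coverage", {
  ch <- make_chain("B2M", sim_config(seed = 1L), SCHEMA)
  hit <- map_to_frame(ch$sequence, SCHEMA$frames$IG_C1)
  sig_cols <- as.character(unique(
    SCHEMA$signatures$position[SCHEMA$signatures$frame == "IG_C1"]))
  hit$position_map[sig_cols] <- NA_integer_
  expect_warning(scores <- score_domain(hit, ch$sequence, SCHEMA),
                 "zero readable signature coverage")
  readable <- attr(scores, "readable_weight")
  expect_true(all(readable[c("B2M", "WA", "WB", "IIA", "IIB", "I_HEAVY")] == 0))
  expect_true(all(scores == 0))
})

test_that("noise-free chains of every class are labeled correctly with margin above tau", {
  for (lab in CLASSES6) {
    call <- call_for(lab, seed = 13L)
    expect_equal(call$label, lab)
    expect_gte(call$margin, 0.15)
    expect_true(all(call$scores >= 0 & call$scores <= 1))
  }
})

test_that("an exactly tied chain is UNKNOWN with margin 0", {
  # two classes claiming different residues at the same single column with
  # equal weight: no chain can separate them when the column matches neither
  toy <- schema_from_list(toy_schema_list(list(
    toy_sig(3L, "W", "WA", weight = 1), toy_sig(3L, "K", "WB", weight = 1),
    toy_sig(7L, "M", "WA", weight = 1), toy_sig(7L, "M", "WB", weight = 1))))
  fr <- toy$frames$IG_C1
  hit <- map_to_frame(fr$consensus, fr)
  hit$chain_id <- "tie"
  arch <- structure(list(chain_id = "tie", domains = list(hit),
                         extracellular_domain_count = 2L, cptmcy_count = 0L,
                         tm_interval = NULL),
                    class = "chain_architecture")
  # consensus column 3 is N (neither W nor K), column 7 is K (not M):
  # both classes score 0/2 -> tie
  call <- classify_chain(arch, fr$consensus, toy)
  expect_equal(call$label, "UNKNOWN")
  expect_equal(call$margin, 0)
})

test_that("signature-free random chains are almost always UNKNOWN", {
  labels <- vapply(1:40, function(i) {
    cfg <- sim_config(seed = 5000L + i, mu = 1, randomize_signatures = TRUE)
    ch <- make_chain(sample(CLASSES6, 1L), cfg, SCHEMA)
    classify_sequences(setNames(ch$sequence, "null"), SCHEMA)$table$label
  }, character(1))
  expect_gte(mean(labels == "UNKNOWN"), 0.95)
})

test_that("interface reports always enumerate exactly the three class I interfaces", {
  wa <- call_for("WA", seed = 21L)
  wb <- call_for("WB", seed = 22L)
  ir <- evaluate_interfaces(wa, wb, SCHEMA)
  expect_named(ir$interfaces, c("A1A2_B2M", "A1A2_A3", "A3_B2M"))

  b2m <- call_for("B2M", seed = 21L)
  heavy <- call_for("I_HEAVY", seed = 22L)
  ir2 <- evaluate_interfaces(b2m, heavy, SCHEMA)
  expect_named(ir2$interfaces, c("A1A2_B2M", "A1A2_A3", "A3_B2M"))
  expect_true(all(vapply(ir2$interfaces, `[[`, character(1), "verdict") ==
                    "CLASS_I_TYPE"))
  # alpha/beta roles are checked
  expect_error(evaluate_interfaces(heavy, b2m, SCHEMA), "alpha chain")
})

test_that("a class II pair shows the class II diagnostic at the alpha1alpha2/alpha3 interface", {
  iia <- call_for("IIA", seed = 31L)
  iib <- call_for("IIB", seed = 32L)
  ir <- evaluate_interfaces(iia, iib, SCHEMA)
  expect_equal(ir$interfaces$A1A2_A3$verdict, "CLASS_II_TYPE")
  expect_false(any(vapply(ir$interfaces, `[[`, character(1), "verdict") ==
                     "CLASS_I_TYPE"))
})

test_that("a gapped position 61 on the beta Ig domain gives an AMBIGUOUS verdict", {
  wa <- call_for("WA", seed = 41L)
  wb <- call_for("WB", seed = 42L)
  ig_idx <- which(vapply(wb$architecture$domains, `[[`, character(1), "frame") ==
                    "IG_C1")
  wb$architecture$domains[[ig_idx]]$position_map["61"] <- NA_integer_
  ir <- evaluate_interfaces(wa, wb, SCHEMA)
  expect_equal(ir$interfaces$A1A2_A3$verdict, "AMBIGUOUS")
})
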