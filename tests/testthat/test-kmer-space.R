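# k-mer space: alphabet reduction, counting, frequency vectors

test_that("alphabet reduction maps residues to their physicochemical class", {
  expect_identical(reduce_alphabet("ALWKD"), "11245")
  expect_identical(reduce_alphabet(""), "")
  expect_identical(reduce_alphabet("DE"), "55")
  expect_identical(reduce_alphabet("AILMPV"), "111111")
  expect_identical(reduce_alphabet("FWY"), "222")
  expect_identical(reduce_alphabet("CGNQST"), "333333")
  expect_identical(reduce_alphabet("HKR"), "444")
  # unknown characters pass through unchanged
  expect_identical(reduce_alphabet("AXB-"), "1XB-")
  # vectorized, length preserved
  expect_identical(nchar(reduce_alphabet(c("ACD", "WWWW"))), c(3L, 4L))
})

test_that("spec dimension and k-mer ordering are canonical", {
  expect_equal(kmer_spec(3)$n, 8000)
  expect_equal(kmer_spec(3, "reduced5")$n, 125)
  expect_warning(sp4 <- kmer_spec(4), "sparse")
  expect_equal(sp4$n, 160000)
  expect_error(kmer_spec(0), "1..4")
  ks <- kmer_strings(kmer_spec(2))
  expect_equal(length(ks), 400)
  expect_identical(ks[1:3], c("AA", "AC", "AD"))  # last char fastest
  expect_identical(ks[400], "YY")
  expect_false(anyDuplicated(ks) > 0)  # bijection
})

test_that("k-mer counting slides windows and filters invalid characters", {
  sp3 <- kmer_spec(3)
  cnt <- count_kmers("ACDEF", sp3)
  ks <- kmer_strings(sp3)
  expect_equal(sum(cnt), 3)
  expect_equal(cnt[match(c("ACD", "CDE", "DEF"), ks)], rep(1L, 3))
  # windows containing any non-canonical character contribute nothing
  expect_equal(sum(count_kmers("AXA", kmer_spec(2))), 0)
  expect_equal(sum(count_kmers("AUA", kmer_spec(2))), 0)  # selenocysteine
  expect_equal(sum(count_kmers("AOA", kmer_spec(2))), 0)  # pyrrolysine
  sp1 <- kmer_spec(1)
  expect_equal(count_kmers("AAA", sp1)[1], 3L)
  # shorter than k: all zero, not an error
  expect_equal(sum(count_kmers("AC", sp3)), 0)
  expect_equal(sum(count_kmers("", sp3)), 0)
})

test_that("counting matches a direct window-scan oracle on random inputs", {
  withr::with_seed(71, {
    for (k in 1:3) {
      spec <- kmer_spec(k)
      for (i in 1:8) {
        s <- rand_aa_seq(sample(3:60, 1), ambig_rate = 0.1)
        expect_equal(count_kmers(s, spec), oracle_count_kmers(s, spec))
        # count conservation: at most one count per window
        expect_lte(sum(count_kmers(s, spec)), max(nchar(s) - k + 1, 0))
      }
    }
  })
})

test_that("protein vectors are normalized frequency vectors", {
  sp3 <- kmer_spec(3)
  v <- protein_vector("ACDEF", sp3)
  expect_equal(v$total_kmers, 3L)
  expect_equal(sum(v$values), 1, tolerance = 1e-9)
  expect_equal(sort(unique(v$values[v$values > 0])), 1 / 3)
  v2 <- protein_vector("AAAA", kmer_spec(2))
  expect_equal(v2$values[1], 1)  # AA is index 1
  v3 <- protein_vector("ACAC", kmer_spec(2))
  ks <- kmer_strings(kmer_spec(2))
  expect_equal(v3$values[match("AC", ks)], 2 / 3)
  expect_equal(v3$values[match("CA", ks)], 1 / 3)
  # no valid windows -> all-zero vector
  v0 <- protein_vector("XXXX", sp3)
  expect_equal(v0$total_kmers, 0L)
  expect_true(all(v0$values == 0))
})

test_that("proteome vectors pool raw counts before normalizing", {
  sp2 <- kmer_spec(2)
  pr <- proteome_record("org1", list(
    protein_record("p1", "AAC"), protein_record("p2", "CA")))
  v <- proteome_vector(pr, sp2)
  ks <- kmer_strings(sp2)
  expect_equal(v$total_kmers, 3L)
  expect_equal(v$values[match(c("AA", "AC", "CA"), ks)], rep(1 / 3, 3))
  # single-protein proteome equals the protein vector
  pr1 <- proteome_record("org2", list(protein_record("p1", "ACDEFG")))
  expect_equal(proteome_vector(pr1, sp2)$values,
               protein_vector("ACDEFG", sp2)$values)
  # pooling is length-weighted, not a mean of per-protein vectors
  prw <- proteome_record("org3", list(
    protein_record("p1", "AAAAAAAAAAA"),        # 10 AA windows
    protein_record("p2", "CC")))                # 1 CC window
  vw <- proteome_vector(prw, sp2)
  expect_equal(vw$values[match("AA", ks)], 10 / 11)
})

test_that("group filters select and complement protein sets", {
  sp1 <- kmer_spec(1)
  pr <- proteome_record("org1", list(
    protein_record("p1", "AA", groups = "g1"),
    protein_record("p2", "CC", groups = "g2")))
  v <- proteome_vector(pr, sp1, groups = "g1")
  expect_equal(v$values[1], 1)  # only A residues
  vc <- proteome_vector(pr, sp1, groups = "g1", exclude = TRUE)
  expect_equal(vc$values[2], 1)  # only C residues
  expect_error(proteome_vector(pr, sp1, groups = "absent"), "no proteins")
})

test_that("reduced-alphabet counting equals reducing then counting 20-letter k-mers", {
  withr::with_seed(72, {
    for (k in 1:3) {
      sp20 <- kmer_spec(k)
      sp5 <- kmer_spec(k, "reduced5")
      ks20 <- kmer_strings(sp20)
      ks5 <- kmer_strings(sp5)
      for (i in 1:5) {
        s <- rand_aa_seq(80)
        c20 <- count_kmers(s, sp20)
        # map each 20-alphabet k-mer to its reduced image and sum counts
        mapped <- tapply(c20, factor(reduce_alphabet(ks20), levels = ks5),
                         sum)
        expect_equal(unname(as.vector(mapped)),
                     count_kmers(reduce_alphabet(s), sp5))
        # protein_vector applies the reduction internally
        expect_equal(protein_vector(s, sp5)$values,
                     protein_vector(reduce_alphabet(s), sp5)$values)
      }
    }
  })
})
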