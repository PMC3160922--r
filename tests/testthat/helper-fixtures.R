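# Shared fixtures, built in code.

# Tiny 3-record, 5-item dataset used by the I/O tests.
toy_dataset <- function() {
  x <- matrix(c(1L, 0L, 1L,
                0L, 1L, NA,
                1L, 1L, 0L,
                0L, 0L, 1L,
                NA, 1L, 0L),
              nrow = 3, dimnames = list(c("d1", "d2", "d3"),
                                        c("a", "b", "c", "d", "e")))
  va_data(x, c("flu", "tb", "flu"), causes = c("flu", "tb"),
          hce = c(FALSE, TRUE, FALSE, FALSE, TRUE))
}

write_toy_csv <- function(dir = withr::local_tempdir(.local_envir = parent.frame())) {
  csv <- file.path(dir, "toy.csv")
  cfg <- file.path(dir, "toy.yaml")
  writeLines(c("death_id,gold_cause,a,b,c,d,e",
               "d1,flu,1,0,1,0,",
               "d2,tb,0,1,1,0,1",
               "d3,flu,1,,0,1,0"), csv)
  yaml::write_yaml(list(causes = list("flu", "tb"),
                        hce_items = list("b", "e")), cfg)
  list(csv = csv, config = cfg)
}

# Expert-style one-vs-all tree: malaria iff fever & convulsions & no stiff
# neck & no bulging fontanelle & no measles; any violated conjunct -> other.
expert_malaria_tree <- function() {
  leaf <- function(lbl) list(leaf = lbl)
  node <- function(item, no, yes) list(item = item, left = no, right = yes)
  nested <- list(
    classes = list("malaria", "other"),
    root = node("fever", leaf("other"),
      node("convulsions", leaf("other"),
        node("stiff_neck",
          node("bulging_fontanelle",
            node("measles", leaf("malaria"), leaf("other")),
            leaf("other")),
          leaf("other"))))
  )
  vaforest:::tree_from_list(nested)
}

# Symptom matrix row for the expert tree's items.
expert_case <- function(fever, convulsions, stiff_neck, bulging_fontanelle,
                        measles) {
  m <- matrix(as.integer(c(fever, convulsions, stiff_neck,
                           bulging_fontanelle, measles)), nrow = 1)
  colnames(m) <- c("fever", "convulsions", "stiff_neck",
                   "bulging_fontanelle", "measles")
  m
}

# A dataset with two perfectly separable causes: item "sig_a" endorsed iff
# cause A, "sig_b" endorsed iff cause B, plus constant filler items.
separable_pair_data <- function(n_per = 10L) {
  n <- 2L * n_per
  x <- cbind(sig_a = rep(c(1L, 0L), each = n_per),
             sig_b = rep(c(0L, 1L), each = n_per),
             fill1 = rep(0L, n), fill2 = rep(1L, n))
  rownames(x) <- sprintf("r%02d", seq_len(n))
  va_data(x, rep(c("A", "B"), each = n_per), causes = c("A", "B"))
}
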