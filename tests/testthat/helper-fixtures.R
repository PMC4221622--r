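# shared fixture builders; everything is generated in code under fixed seeds

random_trait_table <- function(n_groups = 9, n_traits = 82, q_prob = 0.01,
                               seed = 1) {
  withr::with_seed(seed, {
    cells <- matrix(sample(c(0L, 1L), n_groups * n_traits, replace = TRUE),
                    n_groups, n_traits)
    if (q_prob > 0) {
      cells[runif(length(cells)) < q_prob] <- NA_integer_
    }
    cells
  })
  trait_table(cells, paste0("grp", seq_len(n_groups)),
              paste0("tr", seq_len(n_traits)))
}

random_distance_matrix <- function(n = 5, seed = 1, labels = NULL) {
  withr::with_seed(seed, {
    m <- matrix(runif(n * n), n, n)
    m <- (m + t(m)) / 2
    diag(m) <- 0
  })
  pairwise_matrix(m, labels %||% paste0("grp", seq_len(n)),
                  polarity = "distance")
}

`%||%` <- function(a, b) if (is.null(a)) b else a

# independent brute-force Jaccard for one pair, straight from the definition
brute_jaccard_distance <- function(vi, vj, recode = FALSE) {
  if (recode) {
    vi[is.na(vi)] <- 1L
    vj[is.na(vj)] <- 1L
  }
  keep <- !is.na(vi) & !is.na(vj)
  vi <- vi[keep]; vj <- vj[keep]
  a <- sum(vi & vj)
  union_ <- sum(vi | vj)
  1 - a / union_
}

plains_classification <- function() {
  data.frame(
    group = c("Blackfoot", "Sarsi", "GrosVentre", "Assiniboine", "Crow",
              "Cheyenne", "Arapaho", "Teton", "Kiowa"),
    family = c("Algonquian", "Athabaskan", "Algonquian", "Siouan", "Siouan",
               "Algonquian", "Algonquian", "Siouan", "KiowaTanoan"),
    subgroup = c("", "", "Arapahoan", "Dakotan", "", "", "Arapahoan",
                 "Dakotan", ""),
    stringsAsFactors = FALSE
  )
}
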