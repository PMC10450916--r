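# Feature table for a seeded normal vs. microlith phantom cohort, built
# once per test run (in-memory; no files). 48 per group at 64 x 64.
lesion_cohort_features <- local({
  cache <- NULL
  function(n_per_group = 48L, shape = c(64L, 64L), seed = 11L) {
    key <- paste(n_per_group, paste(shape, collapse = "x"), seed)
    if (!is.null(cache) && identical(attr(cache, "key"), key))
      return(cache)
    params <- glcm_params()
    rows <- lapply(seq_len(2L * n_per_group), function(i) {
      lesion <- if (i <= n_per_group) "none" else "microliths"
      label <- if (lesion == "none") "normal" else "microlith"
      img <- make_phantom(phantom_spec(shape = shape, lesion = lesion,
                                       seed = seed * 100000L + i))
      roi <- roi_spec(sprintf("cohort_%03d.png", i), 0, 0,
                      shape[2], shape[1])
      extract_record(img, roi, params,
                     mineralization = label == "microlith",
                     lesion_label = label)
    })
    tbl <- do.call(rbind, rows)
    attr(tbl, "key") <- key
    cache <<- tbl
    tbl
  }
})
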