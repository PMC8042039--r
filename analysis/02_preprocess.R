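#!/usr/bin/env Rscript
# Step 2 — geometric preprocessing of the landmark data.
#
# Excludes specimens missing more than four landmarks, imputes the remaining
# gaps by thin-plate-spline warping from the sample consensus (reference
# re-estimated once), symmetrizes every configuration by joint Procrustes
# alignment with its reflected-relabeled copy, and corrects shapes and
# centroid sizes for sex dimorphism. Fossils are set aside untouched: they
# must not influence the consensus.

library(climorph)

out <- file.path("results", "synthetic_study")
data_dir <- file.path(out, "data")
scheme <- read_scheme(file.path(data_dir, "scheme.yaml"))
configs <- read_landmark_csv(file.path(data_dir, "landmarks.csv"), scheme)

fossil_ids <- c("fossil1", "fossil2")
is_fossil <- vapply(configs, function(cf) cf$group_id %in% fossil_ids,
                    logical(1))
modern <- configs[!is_fossil]

excl <- vapply(modern, is_excluded, logical(1))
cat(sprintf("excluded %d of %d specimens (> 4 missing landmarks)\n",
            sum(excl), length(modern)))
modern <- modern[!excl]

has_miss <- vapply(modern, function(cf) n_missing(cf) > 0, logical(1))
ref <- gpa_align(modern[!has_miss])$consensus
modern[has_miss] <- lapply(modern[has_miss], impute_missing,
                           reference = ref, scheme = scheme)
ref2 <- gpa_align(modern)$consensus
modern[has_miss] <- lapply(modern[has_miss], impute_missing,
                           reference = ref2, scheme = scheme)
cat(sprintf("imputed %d specimens by TPS warping\n", sum(has_miss)))

sym <- symmetrize(modern, scheme)
consensus <- attr(sym, "consensus")
shapes <- do.call(rbind, lapply(sym, function(cf) flatten_coords(cf$coords)))
colnames(shapes) <- coordinate_labels(scheme)
meta <- data.frame(specimen_id = vapply(modern, `[[`, "", "specimen_id"),
                   group_id = vapply(modern, `[[`, "", "group_id"),
                   sex = vapply(modern, `[[`, "", "sex"))
cs <- vapply(modern, function(cf) centroid_size(cf$coords), 0)

# sex correction: remove class means, restore grand mean; keep the male
# offset so fossils (assumed male) can be corrected consistently later
grand <- colMeans(shapes)
male_offset <- grand - colMeans(shapes[meta$sex == "M", , drop = FALSE])
shapes_c <- remove_group_nuisance(shapes, meta$sex)
cs_c <- as.numeric(remove_group_nuisance(cs, meta$sex))

sizes <- do.call(rbind, lapply(modern, function(cf) {
  rs <- region_sizes(cf, scheme)
  cbind(specimen_id = cf$specimen_id, group_id = cf$group_id, sex = cf$sex,
        rs, full_cs = attr(rs, "full_cs"))
}))

write.csv(cbind(meta, full_cs = cs, full_cs_corrected = cs_c, shapes_c),
          file.path(out, "aligned_corrected_shapes.csv"), row.names = FALSE)
write.csv(data.frame(label = scheme$labels, consensus),
          file.path(out, "consensus.csv"), row.names = FALSE)
write.csv(data.frame(coordinate = coordinate_labels(scheme),
                     male_offset = male_offset),
          file.path(out, "male_offset.csv"), row.names = FALSE)
write.csv(sizes, file.path(out, "sizes.csv"), row.names = FALSE)
cat(sprintf("preprocessed %d specimens; consensus and corrected shapes written to %s\n",
            nrow(shapes), out))
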