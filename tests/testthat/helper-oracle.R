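# brute-force rule tables for trio genotype configurations, written as
# literal lookups, independent of the engine's code path

# autosomal diploid trio: 27 configurations -> expected mode ("none" if no
# call should be emitted) and parent of origin
autosomal_trio_oracle <- function() {
  g <- c("hom_ref", "het", "hom_alt")
  grid <- expand.grid(child = g, father = g, mother = g,
                      stringsAsFactors = FALSE)
  mode <- rep("none", nrow(grid))
  origin <- rep(NA_character_, nrow(grid))
  for (i in seq_len(nrow(grid))) {
    ch <- grid$child[i]; fa <- grid$father[i]; mo <- grid$mother[i]
    if (ch == "het" && fa == "hom_ref" && mo == "hom_ref") {
      mode[i] <- "de_novo"; origin[i] <- "none"
    } else if (ch == "het" && fa == "het" && mo == "hom_ref") {
      mode[i] <- "autosomal_dominant"; origin[i] <- "father"
    } else if (ch == "het" && fa == "hom_ref" && mo == "het") {
      mode[i] <- "autosomal_dominant"; origin[i] <- "mother"
    }
    # everything else: untransmitted, ambiguous-origin (both parents
    # carriers), hom-alt child, or hom-alt parent -> no call
  }
  cbind(as.data.table(grid), data.table(mode = mode, origin = origin))
}

# X chromosome, male child (hemizygous states): 12 configurations
x_male_trio_oracle <- function() {
  grid <- expand.grid(child = c("hemi_ref", "hemi_alt"),
                      father = c("hemi_ref", "hemi_alt"),
                      mother = c("hom_ref", "het", "hom_alt"),
                      stringsAsFactors = FALSE)
  mode <- rep("none", nrow(grid))
  origin <- rep(NA_character_, nrow(grid))
  for (i in seq_len(nrow(grid))) {
    ch <- grid$child[i]; fa <- grid$father[i]; mo <- grid$mother[i]
    if (ch == "hemi_alt" && fa == "hemi_ref" && mo == "hom_ref") {
      mode[i] <- "de_novo"; origin[i] <- "none"
    } else if (ch == "hemi_alt" && fa == "hemi_ref" && mo == "het") {
      mode[i] <- "x_linked_recessive"; origin[i] <- "mother"
    }
  }
  cbind(as.data.table(grid), data.table(mode = mode, origin = origin))
}

# X chromosome, female child (diploid): 18 configurations
x_female_trio_oracle <- function() {
  grid <- expand.grid(child = c("hom_ref", "het", "hom_alt"),
                      father = c("hemi_ref", "hemi_alt"),
                      mother = c("hom_ref", "het", "hom_alt"),
                      stringsAsFactors = FALSE)
  mode <- rep("none", nrow(grid))
  origin <- rep(NA_character_, nrow(grid))
  for (i in seq_len(nrow(grid))) {
    ch <- grid$child[i]; fa <- grid$father[i]; mo <- grid$mother[i]
    if (ch == "het" && fa == "hemi_ref" && mo == "hom_ref") {
      mode[i] <- "de_novo"; origin[i] <- "none"
    } else if (ch == "hom_alt" && fa == "hemi_alt" && mo == "het") {
      mode[i] <- "x_linked_recessive"; origin[i] <- "ambiguous"
    }
  }
  cbind(as.data.table(grid), data.table(mode = mode, origin = origin))
}

# two-site compound-het oracle for one gene: the pair is trans-phasable iff
# the child is het at both sites and, at each site, exactly one parent
# carries the allele and the carrying parents differ between the sites
comphet_pair_expected <- function(child1, child2, fa1, fa2, mo1, mo2) {
  carries <- function(gt) gt %in% c("het", "hom_alt", "hemi_alt")
  if (child1 != "het" || child2 != "het") return(FALSE)
  origin_of <- function(fa, mo) {
    f <- carries(fa); m <- carries(mo)
    if (f && !m) "father" else if (m && !f) "mother" else NA_character_
  }
  o1 <- origin_of(fa1, mo1); o2 <- origin_of(fa2, mo2)
  !is.na(o1) && !is.na(o2) && o1 != o2
}
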