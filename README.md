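# fakefoodr

Automated dietary assessment for fake-food buffet (FFB) studies.

The FFB is an established food-choice research method: participants serve
themselves meals from a buffet of replica foods, a photograph is taken, and
the researcher identifies, weighs and nutritionally evaluates every item —
today largely by hand. `fakefoodr` implements the computational backbone
that automates the analysis side of that workflow:

1. **Image-set handling** — paired RGB photographs and pixel-level
   ground-truth label masks (one class index per pixel, class 0 =
   background), a class registry (food classes + palette colours), a
   reproducible 70 / 10 / 20 train / validation / test split, and
   item-region enumeration (4-connected components per class).
2. **Joint data augmentation** — the four-step recipe used to expand a
   training subset for pixel-level deep-learning segmenters: rotations by
   90°, 180° and 270°, a horizontal flip, additive colour noise (applied to
   the image only — ground-truth labels must not change under noise), and a
   border zoom that removes 25 % of each dimension. With the original, each
   training pair yields exactly **seven** variants, so a 121-image study
   with an (85, 12, 24) split expands to exactly **631** images.
3. **Segmentation evaluation** — a pooled pixel confusion matrix
   (`n_ij` = pixels of true class *i* predicted as *j*, `t_i = Σ_j n_ij`)
   and the four standard semantic-segmentation measures:

   * pixel accuracy `Σ_i n_ii / Σ_i t_i`
   * mean accuracy `(1/n_cl) Σ_i n_ii / t_i`
   * mean IU `(1/n_cl) Σ_i n_ii / (t_i + Σ_j n_ji − n_ii)`
   * frequency-weighted IU `(Σ_k t_k)⁻¹ Σ_i t_i n_ii / (t_i + Σ_j n_ji − n_ii)`
4. **StandFood food-name standardization** — links a recognized food-class
   name to a FoodEx2-style catalogue code and food category: rule-based
   part-of-speech profiling (lowercase → tag → lemmatize noun / adjective /
   verb sets), noun-index candidate retrieval, a part-of-speech-weighted
   Jaccard match weight, a Levenshtein edit-distance fallback for names
   with no extractable nouns (e.g. "herring", "French dressing"), a
   lexicon-based food-category classifier (raw / derivative / simple
   composite / aggregated composite), and post-processing rules that
   reconcile the classifier's and the matched entry's categories.
5. **FCDB linkage** — resolved codes are joined to a food composition
   database (nutrients per 100 g), turning recognized pixels into nutrient
   information.
6. **Synthetic fixtures** — a buffet-scene generator with exact ground
   truth, a mask perturber with a designed error rate, a toy catalogue/FCDB,
   and a nearest-palette-colour baseline segmenter, so the entire pipeline
   runs and is testable fully offline.

Training the deep segmentation network itself is out of scope; the pipeline
accepts predictions from any external model as mask PNGs
(`segmenter = "external-mask"`).

## Worked example

```r
library(fakefoodr)

ctl <- toy_catalogue()   # 24 FoodEx2-style entries across all 4 categories
tbl <- toy_fcdb(ctl)     # nutrient record per catalogue code
reg <- toy_registry()    # background + 24 food classes with palette colours

# a synthetic buffet photograph with exact ground truth
sc  <- generate_scene(scene_spec(width = 200, height = 150, n_items = 4, seed = 11), reg)

# image -> predicted mask -> standardized foods -> nutrients
rep <- run_pipeline(sc$image, reg, ctl, tbl)
rep$items[, c("class_name", "pixel_count", "code", "final_category", "linked", "energy_kcal")]
#> # A tibble: 4 × 6
#>   class_name    pixel_count code  final_category linked energy_kcal
#>   <chr>               <int> <chr> <chr>          <lgl>        <dbl>
#> 1 pear                  357 A01AB raw            TRUE           114
#> 2 cucumber              435 A01AE raw            TRUE           225
#> 3 smoked salmon         903 A02BF derivative     TRUE           272
#> 4 white bread           455 A02BG derivative     TRUE           309
```

Each row is one recognized food class: its pixel support in the predicted
mask, the catalogue code it standardized to, its reconciled food category,
and the energy of the linked nutrient record.

Name standardization handles the awkward cases where part-of-speech tagging
finds no noun to search on, by falling back to edit distance:

```r
standardize_food("herring", ctl)
#> <standardized_food> 'herring' -> A01AH ('herrings'), category: raw [levenshtein]
standardize_food("French dressing", ctl)
#> <standardized_food> 'French dressing' -> A02BA ('salad dressing'), category: derivative [levenshtein]

describe_food("pasta", ctl)$alternates[, c("name", "code", "weight", "category")]
#> # A tibble: 3 × 4
#>   name                          code  weight category
#>   <chr>                         <chr>  <dbl> <chr>
#> 1 fresh pasta                   A02BB   0.6  derivative
#> 2 dried pasta                   A02BC   0.6  derivative
#> 3 pasta salad with tuna and egg A04DA   0.25 aggregated composite
```

A too-general query such as "pasta" returns ranked alternates so a user can
disambiguate — fresh and dried pasta have different nutritional profiles.

Segmentation evaluation on a hand confusion matrix:

```r
cm <- confusion_matrix(matrix(c(3, 1, 1, 5), 2, 2, byrow = TRUE))
seg_report(cm)
#> # A tibble: 1 × 4
#>   pixel_accuracy mean_accuracy mean_iu freq_weighted_iu
#>            <dbl>         <dbl>   <dbl>            <dbl>
#> 1            0.8         0.792   0.657            0.669
```

## Command line

A thin CLI over the same functions is installed at `inst/cli/fakefood`:

```sh
Rscript inst/cli/fakefood simulate --out data/sim --n-images 10 --seed 1
Rscript inst/cli/fakefood match --name "herring" --catalogue data/sim/catalogue.csv
Rscript inst/cli/fakefood experiment --config run.yaml
```

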