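{
  "name": "dhq_default_24item",
  "description": "Default 24-item diet habits questionnaire schema: 20 scored items mapped to eight sub-scores, evenly spaced 1-5 points per category ladder, reversal for discretionary items.",
  "items": [
    {
      "item_id": "cereal_highfibre_breakfast_freq",
      "class": "frequency",
      "sub_score": "cereal",
      "scored": true,
      "reversed": false,
      "categories": ["lt1_per_week", "1_2_per_week", "3_4_per_week", "5_per_week", "6_plus_per_week"],
      "points": [1, 2, 3, 4, 5]
    },
    {
      "item_id": "cereal_wholemeal_bread_freq",
      "class": "frequency",
      "sub_score": "cereal",
      "scored": true,
      "reversed": false,
      "categories": ["lt1_per_week", "1_2_per_week", "3_4_per_week", "5_per_week", "6_plus_per_week"],
      "points": [1, 2, 3, 4, 5]
    },
    {
      "item_id": "cereal_other_wholegrain_freq",
      "class": "frequency",
      "sub_score": "cereal",
      "scored": true,
      "reversed": false,
      "categories": ["lt1_per_week", "1_2_per_week", "3_4_per_week", "5_per_week", "6_plus_per_week"],
      "points": [1, 2, 3, 4, 5]
    },
    {
      "item_id": "fruit_quantity",
      "class": "fv_quantity",
      "sub_score": "fruit_veg",
      "scored": true,
      "reversed": false,
      "categories": ["lt1_piece", "1_piece", "1_2_pieces", "2_pieces_most_days", "2_plus_pieces_daily"],
      "points": [1, 2, 3, 4, 5]
    },
    {
      "item_id": "vegetable_quantity",
      "class": "fv_quantity",
      "sub_score": "fruit_veg",
      "scored": true,
      "reversed": false,
      "categories": ["lt1_serve", "1_2_serves", "2_3_serves", "3_4_serves", "5_plus_serves"],
      "points": [1, 2, 3, 4, 5]
    },
    {
      "item_id": "vegetable_types",
      "class": "veg_types",
      "sub_score": "fruit_veg",
      "scored": true,
      "reversed": false,
      "categories": ["none", "1_type", "2_types", "3_types", "4_types", "5_plus_types"],
      "points": [1, 1, 2, 3, 4, 5]
    },
    {
      "item_id": "takeaway_freq",
      "class": "frequency",
      "sub_score": "takeaway",
      "scored": true,
      "reversed": true,
      "categories": ["lt1_per_week", "1_2_per_week", "3_4_per_week", "5_per_week", "6_plus_per_week"],
      "points": [1, 2, 3, 4, 5]
    },
    {
      "item_id": "pastries_sweet_biscuits_freq",
      "class": "frequency",
      "sub_score": "takeaway",
      "scored": true,
      "reversed": true,
      "categories": ["lt1_per_week", "1_2_per_week", "3_4_per_week", "5_per_week", "6_plus_per_week"],
      "points": [1, 2, 3, 4, 5]
    },
    {
      "item_id": "salty_snack_freq",
      "class": "frequency",
      "sub_score": "takeaway",
      "scored": true,
      "reversed": true,
      "categories": ["lt1_per_week", "1_2_per_week", "3_4_per_week", "5_per_week", "6_plus_per_week"],
      "points": [1, 2, 3, 4, 5]
    },
    {
      "item_id": "legumes_freq",
      "class": "frequency",
      "sub_score": "fiber",
      "scored": true,
      "reversed": false,
      "categories": ["lt1_per_week", "1_2_per_week", "3_4_per_week", "5_per_week", "6_plus_per_week"],
      "points": [1, 2, 3, 4, 5]
    },
    {
      "item_id": "nuts_seeds_freq",
      "class": "frequency",
      "sub_score": "fiber",
      "scored": true,
      "reversed": false,
      "categories": ["lt1_per_week", "1_2_per_week", "3_4_per_week", "5_per_week", "6_plus_per_week"],
      "points": [1, 2, 3, 4, 5]
    },
    {
      "item_id": "reduced_fat_dairy_freq",
      "class": "frequency",
      "sub_score": "fat",
      "scored": true,
      "reversed": false,
      "categories": ["lt1_per_week", "1_2_per_week", "3_4_per_week", "5_per_week", "6_plus_per_week"],
      "points": [1, 2, 3, 4, 5]
    },
    {
      "item_id": "cooking_fat_type",
      "class": "fat_choice",
      "sub_score": "fat",
      "scored": true,
      "reversed": false,
      "categories": ["butter_or_lard", "blended_spread", "polyunsat_margarine", "monounsat_oil", "unsat_oil_or_none"],
      "points": [1, 2, 3, 4, 5]
    },
    {
      "item_id": "fish_freq",
      "class": "frequency",
      "sub_score": "omega3",
      "scored": true,
      "reversed": false,
      "categories": ["lt1_per_week", "1_2_per_week", "3_4_per_week", "5_per_week", "6_plus_per_week"],
      "points": [1, 2, 3, 4, 5]
    },
    {
      "item_id": "processed_meat_freq",
      "class": "frequency",
      "sub_score": "omega3",
      "scored": true,
      "reversed": true,
      "categories": ["lt1_per_week", "1_2_per_week", "3_4_per_week", "5_per_week", "6_plus_per_week"],
      "points": [1, 2, 3, 4, 5]
    },
    {
      "item_id": "spread_type",
      "class": "fat_choice",
      "sub_score": "food_choices",
      "scored": true,
      "reversed": false,
      "categories": ["butter_or_lard", "blended_spread", "polyunsat_margarine", "monounsat_spread", "none_or_avocado"],
      "points": [1, 2, 3, 4, 5]
    },
    {
      "item_id": "dressing_type",
      "class": "fat_choice",
      "sub_score": "food_choices",
      "scored": true,
      "reversed": false,
      "categories": ["creamy_dressing", "unspecified_oil_dressing", "polyunsat_dressing", "monounsat_dressing", "none_or_vinegar"],
      "points": [1, 2, 3, 4, 5]
    },
    {
      "item_id": "cooking_sauce_type",
      "class": "fat_choice",
      "sub_score": "food_choices",
      "scored": true,
      "reversed": false,
      "categories": ["cream_based", "cheese_based", "unspecified", "tomato_based", "none_or_vegetable_based"],
      "points": [1, 2, 3, 4, 5]
    },
    {
      "item_id": "cooking_method",
      "class": "preparation",
      "sub_score": "food_preparation",
      "scored": true,
      "reversed": false,
      "categories": ["deep_fried", "shallow_fried", "roasted_in_fat", "grilled_or_stirfry", "steamed_poached_microwaved"],
      "points": [1, 2, 3, 4, 5]
    },
    {
      "item_id": "meat_fat_trim",
      "class": "preparation",
      "sub_score": "food_preparation",
      "scored": true,
      "reversed": false,
      "categories": ["never_trim", "rarely_trim", "sometimes_trim", "often_trim", "always_trim_or_no_meat"],
      "points": [1, 2, 3, 4, 5]
    },
    {
      "item_id": "water_intake",
      "class": "frequency",
      "sub_score": null,
      "scored": false,
      "reversed": false,
      "categories": ["lt2_glasses", "2_4_glasses", "5_6_glasses", "7_8_glasses", "gt8_glasses"],
      "points": [1, 2, 3, 4, 5]
    },
    {
      "item_id": "supplement_use",
      "class": "frequency",
      "sub_score": null,
      "scored": false,
      "reversed": false,
      "categories": ["never", "occasionally", "weekly", "most_days", "daily"],
      "points": [1, 2, 3, 4, 5]
    },
    {
      "item_id": "special_diet",
      "class": "frequency",
      "sub_score": null,
      "scored": false,
      "reversed": false,
      "categories": ["no_special_diet", "low_fat", "vegetarian", "dairy_free", "other"],
      "points": [1, 2, 3, 4, 5]
    },
    {
      "item_id": "meals_out_freq",
      "class": "frequency",
      "sub_score": null,
      "scored": false,
      "reversed": false,
      "categories": ["lt1_per_week", "1_2_per_week", "3_4_per_week", "5_per_week", "6_plus_per_week"],
      "points": [1, 2, 3, 4, 5]
    }
  ]
}
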