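# Declarative column maps for supported food-composition CSV dialects.
# Each dialect maps source columns onto the unified food-record model:
#   id / description / group columns, an energy column with its unit
#   (kJ is converted to kcal at load, 1 kcal = 4.184 kJ), per-100 g nutrient
#   columns with units, and one of three portion-table encodings:
#     pairs   - [description-column, gram-weight-column] pairs
#     serving - a single household serving (label column + gram column)
#     inline  - one column holding "label=grams; label=grams" text
sr:
  id: NDB_No
  description: Shrt_Desc
  group: FdGrp_Desc
  energy: { column: Energ_Kcal, unit: kcal }
  nutrients:
    - { name: protein, column: "Protein_(g)", unit: g }
    - { name: fat, column: "Lipid_Tot_(g)", unit: g }
    - { name: carbohydrate, column: "Carbohydrt_(g)", unit: g }
    - { name: fiber, column: "Fiber_TD_(g)", unit: g }
    - { name: calcium, column: "Calcium_(mg)", unit: mg }
    - { name: iron, column: "Iron_(mg)", unit: mg }
  portions:
    style: pairs
    pairs:
      - [GmWt_Desc1, GmWt_1]
      - [GmWt_Desc2, GmWt_2]
fndds:
  id: "Food code"
  description: "Main food description"
  group: "WWEIA Category description"
  energy: { column: "Energy (kcal)", unit: kcal }
  nutrients:
    - { name: protein, column: "Protein (g)", unit: g }
    - { name: fat, column: "Total Fat (g)", unit: g }
    - { name: carbohydrate, column: "Carbohydrate (g)", unit: g }
    - { name: fiber, column: "Dietary fiber (g)", unit: g }
    - { name: calcium, column: "Calcium (mg)", unit: mg }
    - { name: iron, column: "Iron (mg)", unit: mg }
  portions:
    style: pairs
    pairs:
      - ["Portion description 1", "Portion weight 1 (g)"]
      - ["Portion description 2", "Portion weight 2 (g)"]
branded:
  id: fdc_id
  description: description
  group: branded_food_category
  energy: { column: calories_per_100g, unit: kcal }
  nutrients:
    - { name: protein, column: protein_per_100g, unit: g }
    - { name: fat, column: fat_per_100g, unit: g }
    - { name: carbohydrate, column: carbohydrate_per_100g, unit: g }
    - { name: fiber, column: fiber_per_100g, unit: g }
    - { name: calcium, column: calcium_per_100g, unit: mg }
    - { name: iron, column: iron_per_100g, unit: mg }
  portions:
    style: serving
    label: household_serving_fulltext
    weight: serving_size_g
fao:
  id: Code
  description: "Food name"
  group: Group
  energy: { column: "Energy (kJ)", unit: kJ }
  nutrients:
    - { name: protein, column: "Protein (g)", unit: g }
    - { name: fat, column: "Fat (g)", unit: g }
    - { name: carbohydrate, column: "Carbohydrate (g)", unit: g }
    - { name: fiber, column: "Fibre (g)", unit: g }
    - { name: calcium, column: "Calcium (mg)", unit: mg }
    - { name: iron, column: "Iron (mg)", unit: mg }
  portions:
    style: inline
    column: Portions
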