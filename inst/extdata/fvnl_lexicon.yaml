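# Ingredient-scanning lexicons for fiber/FVNL estimation.
# Matching is case-insensitive substring over ingredient names.
version: lexicon-0.1
fiber_sources:
  - inulin
  - psyllium
  - pectin
  - fructooligosaccharide
  - oligofructose
  - polydextrose
  - resistant dextrin
  - wheat bran
  - oat bran
  - beta-glucan
  - whole grain
  - wholegrain
  - whole wheat
fvnl_tokens:
  # fruit / vegetable / nut / legume name fragments
  - apple
  - orange
  - mango
  - pineapple
  - grape
  - banana
  - berry
  - strawberry
  - lychee
  - longan
  - guava
  - passion fruit
  - coconut
  - lime
  - lemon
  - tomato
  - carrot
  - pumpkin
  - spinach
  - kale
  - celery
  - beetroot
  - corn
  - mushroom
  - onion
  - garlic
  - peanut
  - almond
  - cashew
  - walnut
  - macadamia
  - sesame
  - soybean
  - soy bean
  - mung bean
  - red bean
  - black bean
  - chickpea
  - lentil
  - pea
  - fruit
  - vegetable
concentrated_markers:
  - concentrate
  - concentrated
  - paste
  - powder
minor_additives:
  # ingredients treated as not substantially contributing to product weight
  - salt
  - flavouring
  - flavoring
  - natural flavour
  - citric acid
  - ascorbic acid
  - acidity regulator
  - antioxidant
  - stabilizer
  - stabiliser
  - emulsifier
  - preservative
  - sweetener
  - colour
  - color
  - vitamin
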