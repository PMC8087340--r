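item_id,group,item_class,label
milk,milk,daily,Milk
yogurt,milk,daily,Yogurt
fermented_milk,milk,daily,Fermented milk drinks
citrus_fruit,fruits,daily,Citrus fruit
banana,fruits,daily,Banana
apple_pear,fruits,daily,Apple or pear
stone_fruit,fruits,daily,Stone fruit
other_fruit,fruits,daily,Other fresh fruit
leafy_salad,vegetables,daily,Leafy salad
cooked_vegetables,vegetables,daily,Cooked vegetables
tomato,vegetables,daily,Tomato
carrot_pumpkin,vegetables,daily,Carrot or pumpkin
other_vegetables,vegetables,daily,Other vegetables
bread,cereals,daily,Bread
breakfast_cereal,cereals,daily,Breakfast cereal
pasta,cereals,daily,Pasta
whole_grain,cereals,daily,Whole-grain cereal
other_cereals,cereals,daily,Other cereals and derivatives
olive_oil,olive_oil,daily,Olive oil
white_fish_fresh,white_fish,weekly,Fresh white fish
white_fish_frozen,white_fish,weekly,Frozen white fish
oily_fish,blue_fish,weekly,Oily (blue) fish
canned_fish,blue_fish,weekly,Canned oily fish
shellfish,seafood,weekly,Shellfish
other_seafood,seafood,weekly,Other seafood
rice,rice,weekly,Rice
lentils_chickpeas,legumes,weekly,Lentils or chickpeas
beans,legumes,weekly,Beans
chicken,meats,weekly,Chicken or turkey
beef,meats,weekly,Beef
pork,meats,weekly,Pork
lamb,meats,weekly,Lamb
eggs,meats,weekly,Eggs
rabbit_other_meat,meats,weekly,Rabbit or other meats
nuts,nuts,weekly,Nuts
fresh_cheese,cheeses,weekly,Fresh cheese
cured_cheese,cheeses,weekly,Cured cheese
seed_oils,other_oils,weekly,Seed oils
sugary_soda,soft_drinks,occasional,Sugary soft drinks
sweetened_juice,soft_drinks,occasional,Sweetened juices
butter,butter,occasional,Butter
beer,alcohol,occasional,Beer
wine,alcohol,occasional,Wine
spirits,alcohol,occasional,Spirits
french_fries,french_fries,occasional,French fries
crisps,french_fries,occasional,Potato crisps
pastries,sweetmeats,occasional,Pastries and cakes
cookies,sweetmeats,occasional,Cookies
chocolate,sweetmeats,occasional,Chocolate
candy,sweetmeats,occasional,Candy
cured_sausage,sausage,occasional,Cured sausage and cold cuts
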