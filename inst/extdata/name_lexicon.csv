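rule_id,nova_group,required_terms,any_terms,forbidden_terms,category_scope,note
n4_snacks,4,,snack|snacks|chips|crisps|crackers,,,fatty sweet savory or salty packaged snacks
n4_confectionery,4,,biscuit|biscuits|cookie|cookies|chocolate|chocolates|candy|candies|confectionery|wafer|wafers|praline|pralines|jam|marmalade,,,biscuits chocolates candies and confectionery in general
n4_frozen_desserts,4,,ice cream|frozen dessert|frozen desserts|sorbet,,,ice creams and frozen desserts
n4_soft_drinks,4,,cola|soda|carbonated|soft drink|soft drinks|energy drink|energy drinks|sports drink|sports drinks,,,cola soda and other carbonated soft drinks; energy and sports drinks
n4_instant,4,,instant|powdered|dehydrated|soup|noodles|sauce|sauces|seasoning|seasonings|drink mix|dessert mix|condiment|stock cube|bouillon,,,canned packaged dehydrated instant soups noodles sauces desserts drink mixes and seasonings
n4_sweet_yogurt,4,yogurt,sweetened|flavored|fruit|strawberry|vanilla|cherry|peach|banana|honey|caramel|cocoa,,,sweetened and flavored yogurts including fruit yogurts
n4_dairy_drinks,4,,chocolate milk|dairy drink|dairy drinks|milkshake|flavored milk|condensed milk|evaporated milk|dairy dessert|milk dessert|cream,,,dairy drinks including chocolate milk
n4_sweet_juice,4,juice,sweetened|with sugar|sugared,,,sweetened juices
n4_nectar,4,,nectar|juice drink|fruit drink,,,sweetened juices
n4_margarine,4,,margarine|margarines|spread|spreads,,,margarines and spreads
n4_prepared_dishes,4,,pizza|pasta dish|burger|burgers|hot dog|hot dogs|sausage|sausages|nuggets|fish sticks|fish fingers|ready meal|ready meals|pre prepared|meatballs|salami|mortadella,,,pre-prepared packaged meat fish and vegetable dishes
n4_packaged_bread,4,bread,,fresh|freshly|unpackaged,,packaged breads hamburger and hot dog buns
n4_buns,4,,buns|bun|bagel|bagels|toast|rusks,,,hamburger and hot dog buns
n4_bakery,4,,cake|cakes|cake mix|pastry|pastries|croissant|croissants|muffin|muffins|donut|donuts|doughnut|doughnuts|pie|tart,,,pastries cakes and cake mixes; baked products with additives
n4_breakfast_cereals,4,,breakfast cereal|breakfast cereals|cereal bar|cereal bars|granola|muesli|cornflakes|corn flakes|oat rings|choco pops,,,breakfast cereals and bars
n4_formula_shakes,4,,infant formula|meal replacement|protein shake|slim fast,,,infant formulas and drinks; meal replacement shakes
n4_industrial,4,,extruded|reformed|reconstituted,,,industrial formulations eg extrusion molding preprocessing by frying
n3_preserved_veg,3,,canned|bottled|in brine|brine|pickled|pickles,,,canned or bottled legumes or vegetables preserved in salt or vinegar or by pickling
n3_tomato_paste,3,,tomato paste|tomato extract|tomato concentrate|tomato puree,,,tomato extract pastes or concentrates with salt and/or sugar
n3_fruit_in_syrup,3,,in syrup|in sugar syrup,,,fruits in sugar syrup
n3_cured_meat_fish,3,,jerky|bacon|smoked|cured|ham,,,beef jerky bacon; salted dried smoked or cured meat or fish
n3_salted_goods,3,salted,meat|fish|cod|herring|anchovy|anchovies|nuts|nut|peanuts|almonds|cashews|pistachios|seeds|sunflower seeds,,,salted or sugared nuts and seeds; salted meat or fish
n3_sugared_nuts,3,sugared,nuts|peanuts|almonds|seeds,,,salted or sugared nuts and seeds
n3_canned_fish,3,,sardines|sardine|canned fish|canned tuna,,,canned fish such as sardines and tuna
n3_fresh_bread,3,bread,,,,freshly made unpackaged breads of wheat flour yeast water and salt
n3_alcohol,3,,beer|wine|cider,,,fermented alcoholic beverages beer alcoholic cider wine
n2_oils,2,,olive oil|sunflower oil|corn oil|soybean oil|sesame oil|palm oil|seed oil|vegetable oil|oil,,,oils made from seeds nuts and fruits
n2_sugar,2,,sugar|molasses,without|no added|free,,white brown and other types of sugar and molasses
n2_honey,2,,honey,,,honey extracted from honeycombs
n2_maple,2,,maple syrup,,,syrup extracted from maple trees
n2_starch,2,,starch|starches|cornstarch|corn starch,,,starches extracted from corn and other plants
n2_animal_fat,2,,butter|lard|coconut fat|coconut oil|ghee,peanut|cocoa|almond,,butter lard coconut fat; salted butter combines two culinary ingredients
n2_salt,2,,salt|sea salt|rock salt,,,refined or coarse salt mined or from seawater
n1_fresh_produce,1,,natural|fresh|pasteurized|chilled|frozen|raw|cut,,,natural packaged cut chilled or frozen foods
n1_grains,1,,grain|grains|wheat|oats|oat|barley|rye|rice|corn|bulgur|quinoa|cereals,,,bulk or packaged grains; wheat oats and other cereals
n1_milled,1,,flour|flours|grits|flakes|polenta|couscous|semolina,,,grits flakes and flours incl fortified with iron folic acid
n1_pasta,1,,pasta|spaghetti|macaroni|penne|tagliatelle|orzo,,,dried or fresh pasta couscous and polenta
n1_eggs,1,,egg|eggs,,,eggs
n1_legumes,1,,lentils|chickpeas|beans|legumes|peas|pulses,,,lentils chickpeas beans and other legumes
n1_dried_fruit,1,,dried fruit|dried fruits|raisins|sultanas|prunes|dates|dried apricots|dried figs,,,dried fruits
n1_nuts_seeds,1,,nuts|peanuts|almonds|walnuts|hazelnuts|cashews|pistachios|seeds|sesame|sunflower seeds,salted|sugared|roasted|caramelized,,nuts peanuts and other seeds without salt or sugar
n1_herbs_spices,1,,oregano|pepper|thyme|cinnamon|basil|mint|herbs|spices|paprika|cumin,,,fresh or dried herbs and spices
n1_fungi_algae,1,,mushroom|mushrooms|fungi|algae|seaweed,,,fresh and dried mushrooms and other fungi or algae
n1_meat_fish,1,,meat|beef|pork|veal|lamb|poultry|chicken|turkey|fish|seafood|tuna|salmon|cod|shrimp|squid|octopus|fillet|fillets|steak|steaks,,,fresh chilled or frozen meat poultry fish and seafood
n1_milk_yogurt,1,,milk|yogurt,sweetened|flavored|fruit|chocolate|condensed|evaporated,,fresh or pasteurized milk; yoghurt without sugar
n1_juice,1,juice,,sweetened|sugared,,fresh or pasteurized vegetable or fruit juices with no added sugar
n1_infusions,1,,tea|coffee|herbal infusion|chamomile|infusion,,,tea herbal infusions coffee
n1_water,1,,water|mineral water|spring water|tap water,,,tap spring and mineral water
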